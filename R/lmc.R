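#' Linear model of coregionalization (LMC) for a variable/covariate pair
#'
#' Represents the two direct variograms and the cross-variogram as
#' non-negative-definite combinations of shared structures:
#' `gamma_pq(h) = sum_k B_k[p, q] g_k(h)`, where `g_k` are a nugget
#' structure plus one or more unit-sill structural components with fixed
#' family/range, and every 2x2 coefficient matrix `B_k` is positive
#' semidefinite (so every admissible weighting yields a valid variogram).
#'
#' @param structures List of structure descriptors; each a list with
#'   `family` (`"nugget"`, `"spherical"`, `"exponential"`, `"linear"`,
#'   `"matern_stein"`), and for non-nugget families `range` (and `kappa`
#'   for `matern_stein`). For `"linear"` the basis is `h / ref_dist`.
#' @param B List of 2x2 symmetric PSD coefficient matrices, one per
#'   structure (units: squared permil).
#' @param ref_dist Reference distance used to scale the linear basis (and
#'   as the intrinsic reference sill for covariance evaluation).
#' @return Object of class `lmc_model`.
#' @export
lmc_model <- function(structures, B, ref_dist = NULL) {
  stopifnot(length(structures) == length(B))
  for (k in seq_along(B)) {
    Bk <- B[[k]]
    stopifnot(is.matrix(Bk), all(dim(Bk) == 2))
    if (max(abs(Bk - t(Bk))) > 1e-8) stop_isokrig("B_k must be symmetric", "parameter_error")
    if (min(eigen(Bk, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop_isokrig("B_k must be positive semidefinite", "parameter_error")
    }
  }
  needs_ref <- any(vapply(structures, function(s) s$family == "linear", logical(1)))
  if (needs_ref && is.null(ref_dist)) {
    stop_isokrig("A linear structure needs ref_dist.", "parameter_error")
  }
  structure(
    list(structures = structures, B = B, ref_dist = ref_dist),
    class = "lmc_model"
  )
}

#' @export
print.lmc_model <- function(x, ...) {
  cat("<lmc_model>", length(x$structures), "structures\n")
  for (k in seq_along(x$structures)) {
    s <- x$structures[[k]]
    lbl <- if (s$family == "nugget") "nugget" else {
      sprintf("%s(a = %.4g%s)", s$family, s$range,
              if (!is.null(s$kappa) && is.finite(s$kappa %||% NA))
                sprintf(", kappa = %.3g", s$kappa) else "")
    }
    cat(sprintf("  [%d] %s  B = [%.4g %.4g; %.4g %.4g]\n", k, lbl,
                x$B[[k]][1, 1], x$B[[k]][1, 2], x$B[[k]][2, 1], x$B[[k]][2, 2]))
  }
  invisible(x)
}

# Unit basis value of structure k at lags h.
lmc_basis <- function(s, h, ref_dist) {
  switch(s$family,
    nugget = as.numeric(h > 0),
    linear = h / ref_dist,
    unit_gamma(s$family, h, s$range, s$kappa %||% NA)
  )
}

#' Evaluate an LMC direct or cross semivariance
#'
#' @param lmc An `lmc_model`.
#' @param h Lag distance(s), metres.
#' @param p,q Variable indices (1 = primary, 2 = covariate); `p == q` gives
#'   a direct variogram, `p != q` the cross-variogram.
#' @return Semivariance values (squared permil).
#' @export
lmc_gamma <- function(lmc, h, p = 1, q = 1) {
  stopifnot(inherits(lmc, "lmc_model"))
  out <- numeric(length(h))
  for (k in seq_along(lmc$structures)) {
    out <- out + lmc$B[[k]][p, q] * lmc_basis(lmc$structures[[k]], h, lmc$ref_dist)
  }
  out
}

# Cross-covariance implied by the LMC (bounded + intrinsic-linear handling).
lmc_covariance <- function(lmc, h, p = 1, q = 1) {
  sill <- 0
  for (k in seq_along(lmc$structures)) {
    s <- lmc$structures[[k]]
    top <- if (s$family == "linear") 1 else 1  # unit basis saturates at 1 at ref/inf
    sill <- sill + lmc$B[[k]][p, q] * top
  }
  sill - lmc_gamma(lmc, h, p, q)
}

#' Fit a linear model of coregionalization by iterated WLS with PSD projection
#'
#' Given the empirical direct variograms of the primary variable and the
#' covariate plus their cross-variogram on identical lag bins, fits the
#' per-structure 2x2 coefficient matrices by weighted least squares, then
#' enforces positive semidefiniteness by eigenvalue clipping at zero and
#' refitting (a Goulard-Voltz style sweep, at most `max_iter` iterations,
#' convergence tolerance `tol` on the coefficient change).
#'
#' @param direct_a,direct_b,cross `empirical_variogram` objects on identical
#'   lag bins (primary, covariate, cross).
#' @param structures Shared structures (see [lmc_model()]); typically a
#'   nugget plus the primary variable's selected model family/range.
#' @param max_iter,tol Iteration controls.
#' @return An `lmc_model` with attributes `psd_binding` (logical: was
#'   clipping active at convergence) and `rss`.
#' @export
fit_lmc <- function(direct_a, direct_b, cross, structures,
                    max_iter = 100, tol = 1e-8) {
  if (!all(abs(direct_a$lag - direct_b$lag) < 1e-6) ||
      !all(abs(direct_a$lag - cross$lag) < 1e-6)) {
    stop_isokrig("The three variograms must share identical lag bins.",
                 "alignment_error")
  }
  h <- direct_a$lag
  w <- direct_a$np / h^2
  w <- w / sum(w)
  ref_dist <- max(h) * 1.5
  G <- lapply(structures, lmc_basis, h = h, ref_dist = ref_dist)
  emp <- list(`11` = direct_a$gamma, `22` = direct_b$gamma, `12` = cross$gamma)
  K <- length(structures)
  B <- replicate(K, matrix(0, 2, 2), simplify = FALSE)

  # per-pair weighted projection of the residual onto basis k
  coef_k <- function(resid, k) sum(w * G[[k]] * resid) / sum(w * G[[k]]^2)

  psd_binding <- FALSE
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (k in seq_len(K)) {
      Bk_new <- matrix(0, 2, 2)
      for (pq in list(c(1, 1), c(2, 2), c(1, 2))) {
        p <- pq[1]; q <- pq[2]
        key <- paste0(p, q)
        model_rest <- numeric(length(h))
        for (l in seq_len(K)) {
          if (l != k) model_rest <- model_rest + B[[l]][p, q] * G[[l]]
        }
        Bk_new[p, q] <- coef_k(emp[[key]] - model_rest, k)
      }
      Bk_new[2, 1] <- Bk_new[1, 2]
      # PSD projection: clip negative eigenvalues to zero
      eg <- eigen(Bk_new, symmetric = TRUE)
      if (any(eg$values < 0)) {
        psd_binding <- TRUE
        ev <- pmax(eg$values, 0)
        Bk_new <- eg$vectors %*% diag(ev) %*% t(eg$vectors)
        Bk_new <- (Bk_new + t(Bk_new)) / 2
      }
      # direct sills must be nonnegative even after clipping round-off
      Bk_new[1, 1] <- max(Bk_new[1, 1], 0)
      Bk_new[2, 2] <- max(Bk_new[2, 2], 0)
      delta <- max(delta, max(abs(Bk_new - B[[k]])))
      B[[k]] <- Bk_new
    }
    if (delta < tol * max(1, max(abs(unlist(B))))) break
  }
  fit <- lmc_model(structures, B, ref_dist = ref_dist)
  rss <- 0
  for (pq in list(c(1, 1), c(2, 2), c(1, 2))) {
    key <- paste0(pq[1], pq[2])
    rss <- rss + sum((emp[[key]] - lmc_gamma(fit, h, pq[1], pq[2]))^2)
  }
  attr(fit, "psd_binding") <- psd_binding
  attr(fit, "rss") <- rss
  fit
}

#' Build the default shared structures for an LMC from a fitted direct model
#'
#' A nugget structure plus the structural component of the primary
#' variable's selected variogram model.
#'
#' @param model A fitted `vgm_model` for the primary variable.
#' @return List of structure descriptors for [fit_lmc()].
#' @export
lmc_structures_from_model <- function(model) {
  stopifnot(inherits(model, "vgm_model"))
  st <- list(list(family = "nugget"))
  if (model$family == "linear") {
    st <- c(st, list(list(family = "linear")))
  } else {
    st <- c(st, list(list(family = model$family, range = model$range,
                          kappa = if (is.finite(model$kappa %||% NA)) model$kappa else NULL)))
  }
  st
}
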