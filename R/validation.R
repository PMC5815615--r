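#' Leave-one-out cross-validation of a kriging model
#'
#' For each site, predicts its value from all the other sites with the
#' chosen method and the supplied (pre-fitted) variogram or
#' coregionalization model, which is held fixed across folds. Reports the
#' per-site error and kriging variance together with two global
#' diagnostics: RMSE (permil) and MSDR, the mean of squared errors divided
#' by the corresponding kriging variances. A well-calibrated variogram
#' model yields MSDR close to 1.
#'
#' @param sites Data frame with `x`, `y` (and optionally `site_id`).
#' @param values Numeric vector or column name (permil).
#' @param model_or_lmc A fitted `vgm_model` (`KriO`, `KriL`, `KriQ`) or
#'   `lmc_model` (`CoK`).
#' @param method `"KriO"`, `"KriL"`, `"KriQ"` or `"CoK"`.
#' @param values_covariate Covariate at the data sites (CoK only;
#'   standardized).
#' @param drop_covariate For CoK: if `TRUE` (default, strictly co-located)
#'   the held-out site's covariate observation is removed along with its
#'   primary value; if `FALSE` the covariate remains available there (the
#'   covariate surface, e.g. a DEM, is known everywhere).
#' @return A tibble of class `cv_report` with one row per site
#'   (`site_id`, `observed`, `predicted`, `error`, `variance`) and
#'   attributes `rmse`, `msdr`, `method`.
#' @export
loocv <- function(sites, values, model_or_lmc,
                  method = c("KriO", "KriL", "KriQ", "CoK"),
                  values_covariate = NULL, drop_covariate = TRUE) {
  method <- match.arg(method)
  check_site_table(sites)
  check_no_duplicate_sites(sites)
  z <- resolve_values(sites, values)
  n <- nrow(sites)
  if (n < 5) stop_isokrig("Need at least 5 sites for LOOCV.", "input_error")
  D <- dist_matrix(sites$x, sites$y)

  if (method == "CoK") {
    if (is.null(values_covariate)) stop_isokrig("CoK needs values_covariate.", "input_error")
    stopifnot(inherits(model_or_lmc, "lmc_model"))
    z2 <- resolve_values(sites, values_covariate)
    G11 <- matrix(lmc_gamma(model_or_lmc, as.vector(D), 1, 1), n, n); diag(G11) <- 0
    G22 <- matrix(lmc_gamma(model_or_lmc, as.vector(D), 2, 2), n, n); diag(G22) <- 0
    G12 <- matrix(lmc_gamma(model_or_lmc, as.vector(D), 1, 2), n, n); diag(G12) <- 0
    jit <- 1e-10 * model_sill_guess(model_or_lmc)
    pred <- varr <- numeric(n)
    for (i in seq_len(n)) {
      keep1 <- setdiff(seq_len(n), i)
      keep2 <- if (drop_covariate) keep1 else seq_len(n)
      n1 <- length(keep1); n2 <- length(keep2)
      A11 <- G11[keep1, keep1, drop = FALSE]
      A22 <- G22[keep2, keep2, drop = FALSE]
      A12 <- G12[keep1, keep2, drop = FALSE]
      F1 <- c(rep(1, n1), rep(0, n2)); F2 <- c(rep(0, n1), rep(1, n2))
      A <- rbind(
        cbind(rbind(cbind(A11, A12), cbind(t(A12), A22)), cbind(F1, F2)),
        cbind(t(cbind(F1, F2)), matrix(0, 2, 2))
      )
      rhs <- c(G11[keep1, i], G12[i, keep2], 1, 0)
      sol <- tryCatch(solve_with_jitter(A, rhs, jit, n1 + n2),
                      error = function(e) {
                        stop_isokrig(sprintf("LOOCV fold failed at site %d.", i), "fold_error")
                      })
      pred[i] <- sum(sol[seq_len(n1)] * z[keep1]) + sum(sol[n1 + seq_len(n2)] * z2[keep2])
      varr[i] <- max(sum(sol * rhs), 0)
    }
  } else {
    stopifnot(inherits(model_or_lmc, "vgm_model"))
    G <- matrix(model_gamma(model_or_lmc, as.vector(D)), n, n); diag(G) <- 0
    ord <- switch(method, KriO = NULL, KriL = 1, KriQ = 2)
    if (is.null(ord)) {
      F <- matrix(1, n, 1)
    } else {
      F <- trend_basis(sites$x, sites$y, ord)
    }
    p <- ncol(F)
    jit <- 1e-10 * model_sill_guess(model_or_lmc)
    pred <- varr <- numeric(n)
    for (i in seq_len(n)) {
      keep <- setdiff(seq_len(n), i)
      A <- rbind(cbind(G[keep, keep, drop = FALSE], F[keep, , drop = FALSE]),
                 cbind(t(F[keep, , drop = FALSE]), matrix(0, p, p)))
      rhs <- c(G[keep, i], F[i, ])
      sol <- tryCatch(solve_with_jitter(A, rhs, jit, n - 1L),
                      error = function(e) {
                        stop_isokrig(sprintf("LOOCV fold failed at site %d.", i), "fold_error")
                      })
      pred[i] <- sum(sol[seq_len(n - 1L)] * z[keep])
      varr[i] <- max(sum(sol * rhs), 0)
    }
  }

  err <- z - pred
  out <- tibble::tibble(
    site_id = if ("site_id" %in% names(sites)) sites$site_id else as.character(seq_len(n)),
    observed = z, predicted = pred, error = err, variance = varr
  )
  attr(out, "rmse") <- sqrt(mean(err^2))
  attr(out, "msdr") <- mean(err^2 / varr)
  attr(out, "method") <- method
  class(out) <- c("cv_report", class(out))
  out
}

#' Rank cross-validated kriging methods
#'
#' Orders CV reports by how close their MSDR is to the ideal value 1
#' (primary criterion); near-ties in `|MSDR - 1|` (difference below
#' `msdr_tol`) are broken by lower RMSE, then input order. RMSE is always
#' reported alongside.
#'
#' @param reports List of `cv_report` objects (or a single one).
#' @param msdr_tol Tie tolerance on `|MSDR - 1|` (default 0.005).
#' @return A tibble ordered best-first with columns `method`, `rmse`,
#'   `msdr`, `msdr_dist`, `rank`, `selected`.
#' @export
rank_models <- function(reports, msdr_tol = 0.005) {
  if (inherits(reports, "cv_report")) reports <- list(reports)
  stopifnot(length(reports) >= 1)
  tbl <- tibble::tibble(
    method = unname(vapply(reports, function(r) attr(r, "method") %||% "?", "")),
    rmse = unname(vapply(reports, function(r) attr(r, "rmse"), 0)),
    msdr = unname(vapply(reports, function(r) attr(r, "msdr"), 0)),
    input_order = seq_along(reports)
  )
  tbl$msdr_dist <- abs(tbl$msdr - 1)
  # group near-ties on the MSDR criterion, then order by RMSE inside groups
  key <- round(tbl$msdr_dist / msdr_tol)
  ord <- order(key, tbl$rmse, tbl$input_order)
  tbl <- tbl[ord, c("method", "rmse", "msdr", "msdr_dist")]
  tbl$rank <- seq_len(nrow(tbl))
  tbl$selected <- tbl$rank == 1
  tbl
}
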