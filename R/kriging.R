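# Exact BLUP solvers in semivariance form. The kriging system is
#   [ Gamma  F ] [lambda]   [gamma0]
#   [ F'     0 ] [  mu  ] = [  f0  ]
# with Gamma the site-pair semivariance matrix (zero diagonal), F the
# unbiasedness constraint basis (a 1-column for the constant mean of
# ordinary kriging; coordinate monomials for universal kriging), and
#   sigma^2 = lambda' gamma0 + mu' f0.
# The semivariance formulation handles the unbounded linear model natively.

new_kriging_solution <- function(weights, mu, prediction, variance,
                                 weights_covariate = NULL) {
  structure(
    list(weights = weights, weights_covariate = weights_covariate,
         mu = mu, prediction = prediction,
         variance = max(variance, 0)),
    class = "kriging_solution"
  )
}

#' @export
print.kriging_solution <- function(x, ...) {
  cat(sprintf("<kriging_solution> prediction %.6g, variance %.6g, %d weights\n",
              x$prediction, x$variance, length(x$weights)))
  invisible(x)
}

check_no_duplicate_sites <- function(sites) {
  key <- paste(sites$x, sites$y, sep = "_")
  if (anyDuplicated(key)) {
    stop_isokrig("Duplicate site coordinates; deduplicate before kriging.",
                 "duplicate_sites")
  }
}

solve_with_jitter <- function(A, b, jitter_scale, n_data) {
  out <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(out)) {
    idx <- seq_len(n_data)
    A[cbind(idx, idx)] <- A[cbind(idx, idx)] + jitter_scale
    out <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(out)) {
      stop_isokrig("Kriging system is singular even after diagonal jitter.",
                   "numeric_error")
    }
  }
  out
}

model_sill_guess <- function(model) {
  if (inherits(model, "lmc_model")) {
    return(sum(vapply(model$B, function(b) abs(b[1, 1]), 0)))
  }
  if (model$family == "linear") model$nugget + model$slope * 1e4 else model$nugget + model$psill
}

# Shared OK/UK machinery. trend_order NULL => ordinary kriging.
krige_core <- function(sites, values, model, targets, trend_order = NULL) {
  check_site_table(sites)
  check_no_duplicate_sites(sites)
  values <- resolve_values(sites, values)
  n <- nrow(sites)
  if (n < 2) stop_isokrig("Need at least two sites.", "input_error")
  D <- dist_matrix(sites$x, sites$y)
  G <- matrix(model_gamma(model, as.vector(D)), n, n)
  diag(G) <- 0
  if (is.null(trend_order)) {
    F <- matrix(1, n, 1)
    center <- c(mean(sites$x), mean(sites$y)); scale <- 1
    f_at <- function(x, y) matrix(1, length(x), 1)
  } else {
    Xb <- trend_basis(sites$x, sites$y, trend_order)
    if (n <= ncol(Xb) + 1) stop_isokrig("Too few sites for this trend order.", "input_error")
    if (qr(Xb)$rank < ncol(Xb)) stop_isokrig("Trend basis rank deficient.", "collinearity_error")
    F <- Xb
    center <- attr(Xb, "center"); scale <- attr(Xb, "scale")
    f_at <- function(x, y) trend_basis(x, y, trend_order, center = center, scale = scale)
  }
  p <- ncol(F)
  A <- rbind(cbind(G, F), cbind(t(F), matrix(0, p, p)))
  tx <- targets$x; ty <- targets$y
  m <- length(tx)
  Dx <- outer(sites$x, tx, function(a, b) a - b)
  Dy <- outer(sites$y, ty, function(a, b) a - b)
  g0 <- matrix(model_gamma(model, sqrt(as.vector(Dx^2 + Dy^2))), n, m)
  f0 <- t(f_at(tx, ty))
  rhs <- rbind(g0, f0)
  sol <- solve_with_jitter(A, rhs, 1e-10 * model_sill_guess(model), n)
  lambda <- sol[seq_len(n), , drop = FALSE]
  mu <- sol[n + seq_len(p), , drop = FALSE]
  pred <- drop(crossprod(lambda, values))
  varr <- colSums(sol * rhs)
  list(lambda = lambda, mu = mu, prediction = pred, variance = pmax(varr, 0))
}

as_target_df <- function(target) {
  if (is.data.frame(target)) {
    check_site_table(target)
    target[, c("x", "y")]
  } else {
    data.frame(x = target[1], y = target[2])
  }
}

#' Ordinary kriging prediction at a point
#'
#' Solves the (n+1) ordinary-kriging system in semivariance form; weights
#' sum to one. Prediction at a data location reproduces the datum with zero
#' kriging variance (exact-interpolator convention, also with a nonzero
#' nugget).
#'
#' @param sites Data frame with `x`, `y` (projected metres), duplicate-free.
#' @param values Numeric vector or column name (permil).
#' @param model A fitted `vgm_model`.
#' @param target Length-2 numeric `c(x, y)` or a 1-row data frame.
#' @return A `kriging_solution`: `weights`, `mu`, `prediction`, `variance`.
#' @examples
#' s <- data.frame(x = c(0, 10), y = c(0, 0))
#' m <- vgm_model("linear", nugget = 0, slope = 1)
#' ok_predict(s, c(0, 2), m, c(5, 0)) # prediction 1, variance 5
#' @export
ok_predict <- function(sites, values, model, target) {
  tg <- as_target_df(target)
  r <- krige_core(sites, values, model, tg[1, , drop = FALSE], trend_order = NULL)
  new_kriging_solution(drop(r$lambda), drop(r$mu), r$prediction[1], r$variance[1])
}

#' Universal kriging prediction at a point
#'
#' Ordinary kriging augmented with unbiasedness constraints for each
#' monomial of the coordinates up to `trend_order` (linear: `1, x, y`;
#' quadratic adds `x^2, xy, y^2`), so polynomial surfaces of that order are
#' reproduced exactly.
#'
#' @inheritParams ok_predict
#' @param trend_order 1 (linear) or 2 (quadratic).
#' @return A `kriging_solution`.
#' @export
uk_predict <- function(sites, values, model, target, trend_order = 1) {
  stopifnot(trend_order %in% 1:2)
  tg <- as_target_df(target)
  r <- krige_core(sites, values, model, tg[1, , drop = FALSE], trend_order = trend_order)
  new_kriging_solution(drop(r$lambda), drop(r$mu), r$prediction[1], r$variance[1])
}

# Cokriging system builder shared by cok_predict / grids / LOOCV.
# cov_target: optional covariate value at the target (collocated mode).
cok_core <- function(sites, values_primary, values_covariate, lmc, targets,
                     cov_target = NULL) {
  check_site_table(sites)
  check_no_duplicate_sites(sites)
  z1 <- resolve_values(sites, values_primary)
  z2 <- resolve_values(sites, values_covariate)
  n <- nrow(sites)
  D <- dist_matrix(sites$x, sites$y)
  G11 <- matrix(lmc_gamma(lmc, as.vector(D), 1, 1), n, n); diag(G11) <- 0
  G22 <- matrix(lmc_gamma(lmc, as.vector(D), 2, 2), n, n); diag(G22) <- 0
  G12 <- matrix(lmc_gamma(lmc, as.vector(D), 1, 2), n, n)
  diag(G12) <- 0
  tx <- targets$x; ty <- targets$y
  m <- length(tx)
  collocated <- !is.null(cov_target)
  n2 <- if (collocated) n + 1L else n
  build_and_solve <- function(j) {
    d0 <- dist_to_point(sites$x, sites$y, tx[j], ty[j])
    if (collocated) {
      cx2 <- c(sites$x, tx[j]); cy2 <- c(sites$y, ty[j])
      # covariate block including the target-located covariate observation
      D22 <- dist_matrix(cx2, cy2)
      G22a <- matrix(lmc_gamma(lmc, as.vector(D22), 2, 2), n2, n2); diag(G22a) <- 0
      D12 <- sqrt(outer(sites$x, cx2, "-")^2 + outer(sites$y, cy2, "-")^2)
      G12a <- matrix(lmc_gamma(lmc, as.vector(D12), 1, 2), n, n2)
      z2a <- c(z2, cov_target[j])
    } else {
      G22a <- G22; G12a <- G12; z2a <- z2
    }
    F1 <- c(rep(1, n), rep(0, n2)); F2 <- c(rep(0, n), rep(1, n2))
    A <- rbind(
      cbind(rbind(cbind(G11, G12a), cbind(t(G12a), G22a)), cbind(F1, F2)),
      cbind(t(cbind(F1, F2)), matrix(0, 2, 2))
    )
    g10 <- lmc_gamma(lmc, d0, 1, 1)
    d20 <- if (collocated) dist_to_point(cx2, cy2, tx[j], ty[j]) else d0
    g20 <- lmc_gamma(lmc, d20, 1, 2)
    rhs <- c(g10, g20, 1, 0)
    sol <- solve_with_jitter(A, rhs, 1e-10 * model_sill_guess(lmc), n + n2)
    l1 <- sol[seq_len(n)]
    l2 <- sol[n + seq_len(n2)]
    mu <- sol[n + n2 + 1:2]
    pred <- sum(l1 * z1) + sum(l2 * z2a)
    varr <- sum(sol * rhs)
    list(l1 = l1, l2 = l2, mu = mu, prediction = pred, variance = max(varr, 0))
  }
  lapply(seq_len(m), build_and_solve)
}

#' Co-located cokriging prediction at a point
#'
#' Joint BLUP of the primary variable using a correlated, co-located
#' covariate (typically standardized altitude) under a fitted linear model
#' of coregionalization. The system carries two unbiasedness constraints:
#' primary weights sum to 1, covariate weights sum to 0. If
#' `cov_target` is supplied, the covariate value at the target location is
#' included as an extra covariate observation (collocated mode, e.g. when a
#' full-resolution DEM is available).
#'
#' @inheritParams ok_predict
#' @param values_primary,values_covariate Numeric vectors (or column names)
#'   observed at the same sites; the covariate should be standardized.
#' @param lmc A fitted `lmc_model` (primary = variable 1, covariate = 2).
#' @param cov_target Optional covariate value at the target (collocated
#'   mode).
#' @return A `kriging_solution` (`weights` = primary weights,
#'   `weights_covariate` = covariate weights).
#' @export
cok_predict <- function(sites, values_primary, values_covariate, lmc, target,
                        cov_target = NULL) {
  stopifnot(inherits(lmc, "lmc_model"))
  tg <- as_target_df(target)
  r <- cok_core(sites, values_primary, values_covariate, lmc,
                tg[1, , drop = FALSE],
                cov_target = if (is.null(cov_target)) NULL else cov_target[1])[[1]]
  new_kriging_solution(r$l1, r$mu, r$prediction, r$variance,
                       weights_covariate = r$l2)
}

#' Kriging prediction over a raster grid
#'
#' Predicts at the centre of every non-`NA` cell of `grid` with the chosen
#' method, returning prediction and kriging-variance rasters (nodata is
#' propagated).
#'
#' @inheritParams ok_predict
#' @param model_or_lmc A `vgm_model` (KriO/KriL/KriQ) or `lmc_model` (CoK).
#' @param method One of `"KriO"`, `"KriL"`, `"KriQ"`, `"CoK"`.
#' @param grid An `iso_raster` mask: cells with `NA` are skipped.
#' @param values_covariate Covariate at the data sites (CoK only).
#' @param covariate_grid Optional `iso_raster` of covariate values on the
#'   prediction grid (CoK collocated mode).
#' @return List with `prediction` and `variance` rasters.
#' @export
predict_grid <- function(sites, values, model_or_lmc,
                         method = c("KriO", "KriL", "KriQ", "CoK"),
                         grid, values_covariate = NULL, covariate_grid = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(grid, "iso_raster"))
  cells <- as_tibble.iso_raster(grid)
  live <- which(!is.na(cells$value))
  pred_m <- matrix(NA_real_, nrow(grid$values), ncol(grid$values))
  var_m <- pred_m
  if (length(live) == 0L) {
    warning("Grid mask has no valid cells; returning empty rasters.")
    return(list(prediction = iso_raster(pred_m, grid$x0, grid$y0, grid$cell, grid$nodata),
                variance = iso_raster(var_m, grid$x0, grid$y0, grid$cell, grid$nodata)))
  }
  tg <- data.frame(x = cells$x[live], y = cells$y[live])
  if (method == "CoK") {
    if (is.null(values_covariate)) stop_isokrig("CoK needs values_covariate.", "input_error")
    covt <- NULL
    if (!is.null(covariate_grid)) {
      covt <- extract_raster_at_points(covariate_grid, tg)$value
    }
    rs <- cok_core(sites, values, values_covariate, model_or_lmc, tg, cov_target = covt)
    preds <- vapply(rs, function(r) r$prediction, 0)
    vars <- vapply(rs, function(r) r$variance, 0)
  } else {
    ord <- switch(method, KriO = NULL, KriL = 1, KriQ = 2)
    r <- krige_core(sites, values, model_or_lmc, tg, trend_order = ord)
    preds <- r$prediction
    vars <- r$variance
  }
  nr <- nrow(grid$values)
  col <- floor((tg$x - grid$x0) / grid$cell) + 1
  row <- nr - (floor((tg$y - grid$y0) / grid$cell) + 1) + 1
  pred_m[cbind(row, col)] <- preds
  var_m[cbind(row, col)] <- vars
  list(
    prediction = iso_raster(pred_m, grid$x0, grid$y0, grid$cell, grid$nodata),
    variance = iso_raster(var_m, grid$x0, grid$y0, grid$cell, grid$nodata)
  )
}
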