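#' Empirical (experimental) variogram
#'
#' Bins squared half-differences of a per-site variable by separation
#' distance: `gamma_hat(h) = sum (z_i - z_j)^2 / (2 N(h))` over pairs whose
#' distance falls in the bin `(k-1, k] * lag_width`. With `direction`, only
#' pairs whose bearing (degrees clockwise from north, modulo 180) lies
#' within `tol` of `direction` are kept.
#'
#' @param sites Data frame with columns `x`, `y` (metres).
#' @param values Numeric vector, one value per site (permil). Alternatively
#'   the (quoted) name of a column of `sites`.
#' @param lag_width Bin width in metres (default 2500, the average data
#'   spacing used throughout).
#' @param max_dist Maximum pair distance considered; default one third of
#'   the maximum inter-site distance.
#' @param direction,tol Optional directional filtering (degrees).
#' @return A tibble of class `empirical_variogram` with columns `lag`
#'   (mean pair distance per bin), `gamma`, `np`; bin geometry kept as
#'   attributes.
#' @export
empirical_variogram <- function(sites, values, lag_width = 2500,
                                max_dist = NULL, direction = NULL, tol = 22.5) {
  check_site_table(sites)
  values <- resolve_values(sites, values)
  n <- nrow(sites)
  if (n < 2) stop_isokrig("Need at least two sites.", "input_error")
  if (n < 10) warning("Fewer than 10 sites: empirical variogram will be unstable.")
  pr <- site_pairs(sites, values)
  if (is.null(max_dist)) max_dist <- max(pr$h) / 3
  keep <- pr$h > 0 & pr$h <= max_dist
  if (!is.null(direction)) {
    ang_diff <- abs(((pr$bearing - direction + 90) %% 180) - 90)
    keep <- keep & ang_diff <= tol
  }
  pr <- pr[keep, , drop = FALSE]
  if (nrow(pr) == 0) stop_isokrig("No site pairs within max_dist.", "empty_variogram")
  bin <- ceiling(pr$h / lag_width)
  sq <- (pr$za - pr$zb)^2
  np <- tapply(sq, bin, length)
  gam <- tapply(sq, bin, sum) / (2 * np)
  lag <- tapply(pr$h, bin, mean)
  ord <- order(as.numeric(names(np)))
  out <- tibble::tibble(
    lag = as.numeric(lag[ord]),
    gamma = as.numeric(gam[ord]),
    np = as.integer(np[ord])
  )
  attr(out, "lag_width") <- lag_width
  attr(out, "max_dist") <- max_dist
  attr(out, "direction") <- direction
  attr(out, "tol") <- if (is.null(direction)) NULL else tol
  attr(out, "type") <- "direct"
  class(out) <- c("empirical_variogram", class(out))
  out
}

#' Empirical cross-variogram of two co-located variables
#'
#' `gamma_ab(h) = sum (a_i - a_j)(b_i - b_j) / (2 N(h))`; may be negative.
#' Both variables must be observed at the same sites.
#'
#' @inheritParams empirical_variogram
#' @param values_a,values_b Numeric vectors (or column names) of the two
#'   co-located variables.
#' @return A tibble of class `empirical_variogram` (`type = "cross"`).
#' @export
cross_variogram <- function(sites, values_a, values_b, lag_width = 2500,
                            max_dist = NULL) {
  check_site_table(sites)
  if ((is.numeric(values_a) && length(values_a) != nrow(sites)) ||
      (is.numeric(values_b) && length(values_b) != nrow(sites))) {
    stop_isokrig("Both variables must be observed at every site (co-located).",
                 "alignment_error")
  }
  values_a <- resolve_values(sites, values_a)
  values_b <- resolve_values(sites, values_b)
  pr <- site_pairs(sites, values_a, values_b)
  if (is.null(max_dist)) max_dist <- max(pr$h) / 3
  pr <- pr[pr$h > 0 & pr$h <= max_dist, , drop = FALSE]
  if (nrow(pr) == 0) stop_isokrig("No site pairs within max_dist.", "empty_variogram")
  bin <- ceiling(pr$h / lag_width)
  cr <- (pr$za - pr$zb) * (pr$wa - pr$wb)
  np <- tapply(cr, bin, length)
  gam <- tapply(cr, bin, sum) / (2 * np)
  lag <- tapply(pr$h, bin, mean)
  ord <- order(as.numeric(names(np)))
  out <- tibble::tibble(
    lag = as.numeric(lag[ord]),
    gamma = as.numeric(gam[ord]),
    np = as.integer(np[ord])
  )
  attr(out, "lag_width") <- lag_width
  attr(out, "max_dist") <- max_dist
  attr(out, "type") <- "cross"
  class(out) <- c("empirical_variogram", class(out))
  out
}

# All unordered site pairs with distance, bearing and end values.
site_pairs <- function(sites, values, values2 = NULL) {
  n <- nrow(sites)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ij[, 1]; j <- ij[, 2]
  dx <- sites$x[j] - sites$x[i]
  dy <- sites$y[j] - sites$y[i]
  out <- data.frame(
    h = sqrt(dx^2 + dy^2),
    bearing = (atan2(dx, dy) * 180 / pi) %% 180,
    za = values[i], zb = values[j]
  )
  if (!is.null(values2)) { out$wa <- values2[i]; out$wb <- values2[j] }
  out
}

resolve_values <- function(sites, values) {
  if (is.character(values) && length(values) == 1) {
    if (!values %in% names(sites)) {
      stop_isokrig(paste0("Column not found: ", values), "schema_error")
    }
    values <- sites[[values]]
  }
  if (length(values) != nrow(sites)) {
    stop_isokrig("values must have one entry per site.", "input_error")
  }
  as.numeric(values)
}

#' Variogram map (anisotropy surface)
#'
#' Bins semivariance by lag *vector* `(dx, dy)` on a square grid of cell
#' size `cell`; each unordered pair contributes to both `(dx, dy)` and
#' `(-dx, -dy)`, so the map is centro-symmetric by construction. Used to
#' diagnose directional (zonal/geometric) anisotropy.
#'
#' @inheritParams empirical_variogram
#' @param cell Cell size of the lag grid, metres.
#' @return Tibble with columns `dx`, `dy`, `gamma`, `np`.
#' @export
variogram_map <- function(sites, values, cell = 2500, max_dist = NULL) {
  check_site_table(sites)
  values <- resolve_values(sites, values)
  n <- nrow(sites)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ij[, 1]; j <- ij[, 2]
  dx <- sites$x[j] - sites$x[i]
  dy <- sites$y[j] - sites$y[i]
  h <- sqrt(dx^2 + dy^2)
  if (is.null(max_dist)) max_dist <- max(h) / 2
  keep <- h > 0 & h <= max_dist
  sq <- (values[i] - values[j])^2 / 2
  # both orientations of each pair
  DX <- c(dx[keep], -dx[keep]); DY <- c(dy[keep], -dy[keep]); SQ <- c(sq[keep], sq[keep])
  cx <- round(DX / cell); cy <- round(DY / cell)
  key <- paste(cx, cy)
  np <- tapply(SQ, key, length)
  gam <- tapply(SQ, key, mean)
  ks <- strsplit(names(np), " ")
  tibble::tibble(
    dx = as.numeric(vapply(ks, `[`, "", 1)) * cell,
    dy = as.numeric(vapply(ks, `[`, "", 2)) * cell,
    gamma = as.numeric(gam),
    np = as.integer(np)
  )
}

#' Fit and remove a polynomial spatial trend
#'
#' Ordinary least squares of the variable on monomials of the (centred,
#' scaled) coordinates up to `order`: linear uses `1, x, y`; quadratic adds
#' `x^2, xy, y^2`. Residuals feed the detrended variogram; coefficients are
#' reported on the raw coordinate scale.
#'
#' @param sites Data frame with `x`, `y`.
#' @param values Numeric vector or column name.
#' @param order Trend order, 0 (mean only), 1 or 2.
#' @return List of class `trend_model`: `order`, `coefficients` (raw scale),
#'   `residuals`, `fitted`, `sigma2` (residual variance).
#' @export
fit_trend <- function(sites, values, order = 1) {
  check_site_table(sites)
  values <- resolve_values(sites, values)
  stopifnot(order %in% 0:2)
  X <- trend_basis(sites$x, sites$y, order)
  if (nrow(X) <= ncol(X)) stop_isokrig("Too few sites for this trend order.", "input_error")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop_isokrig("Trend basis is rank deficient.", "collinearity_error")
  beta <- qr.coef(qrX, values)
  fit <- drop(X %*% beta)
  res <- values - fit
  structure(
    list(order = order, coefficients = beta,
         coefficients_raw = raw_trend_coefs(beta, order,
                                            attr(X, "center"), attr(X, "scale")),
         residuals = res, fitted = fit,
         sigma2 = sum(res^2) / max(length(res) - ncol(X), 1),
         center = attr(X, "center"), scale = attr(X, "scale")),
    class = "trend_model"
  )
}

# Expand coefficients fitted on centred/scaled coordinates back to the
# raw-coordinate polynomial (orders 0-2).
raw_trend_coefs <- function(beta, order, center, scale) {
  cx <- center[1]; cy <- center[2]; s <- scale
  out <- c(`(Intercept)` = 0, x = 0, y = 0, x2 = 0, xy = 0, y2 = 0)
  out["(Intercept)"] <- beta[1]
  if (order >= 1) {
    a1 <- beta["x"]; a2 <- beta["y"]
    out["(Intercept)"] <- out["(Intercept)"] - a1 * cx / s - a2 * cy / s
    out["x"] <- a1 / s
    out["y"] <- a2 / s
  }
  if (order == 2) {
    a3 <- beta["x2"]; a4 <- beta["xy"]; a5 <- beta["y2"]
    out["(Intercept)"] <- out["(Intercept)"] +
      (a3 * cx^2 + a4 * cx * cy + a5 * cy^2) / s^2
    out["x"] <- out["x"] - (2 * a3 * cx + a4 * cy) / s^2
    out["y"] <- out["y"] - (2 * a5 * cy + a4 * cx) / s^2
    out["x2"] <- a3 / s^2
    out["xy"] <- a4 / s^2
    out["y2"] <- a5 / s^2
  }
  keep <- switch(as.character(order), "0" = 1, "1" = 1:3, "2" = 1:6)
  out[keep]
}

#' Predict a fitted spatial trend at new locations
#'
#' @param object A `trend_model` from [fit_trend()].
#' @param newdata Data frame with `x`, `y`.
#' @param ... Unused.
#' @return Numeric vector of trend values.
#' @export
predict.trend_model <- function(object, newdata, ...) {
  X <- trend_basis(newdata$x, newdata$y, object$order,
                   center = object$center, scale = object$scale)
  drop(X %*% object$coefficients)
}

# Monomial basis on centred/scaled coordinates (conditioning: raw UTM
# coordinates are ~1e5-1e6 m, so x^2 would be ~1e12).
trend_basis <- function(x, y, order, center = NULL, scale = NULL) {
  if (is.null(center)) center <- c(mean(x), mean(y))
  if (is.null(scale)) {
    scale <- max(stats::sd(x), stats::sd(y), 1)
  }
  u <- (x - center[1]) / scale
  v <- (y - center[2]) / scale
  X <- switch(as.character(order),
    "0" = cbind(`(Intercept)` = rep(1, length(u))),
    "1" = cbind(`(Intercept)` = 1, x = u, y = v),
    "2" = cbind(`(Intercept)` = 1, x = u, y = v, x2 = u^2, xy = u * v, y2 = v^2)
  )
  attr(X, "center") <- center
  attr(X, "scale") <- scale
  X
}
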