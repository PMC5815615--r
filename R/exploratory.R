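#' Descriptive statistics with a normality gate
#'
#' Mean, sample SD, min, max, adjusted Fisher-Pearson skewness, excess
#' kurtosis and the Shapiro-Wilk normality test for each requested column.
#' Kriging assumes approximately Gaussian variables, so this is the
#' screening step run before any variogram modelling.
#'
#' @param data Data frame.
#' @param cols Character vector of numeric column names (default: all
#'   numeric columns).
#' @return Tibble with one row per variable: `variable`, `n`, `mean`, `sd`,
#'   `min`, `max`, `skewness`, `kurtosis_excess`, `shapiro_w`, `shapiro_p`,
#'   `normality_defined`.
#' @export
describe_variables <- function(data, cols = NULL) {
  stopifnot(is.data.frame(data))
  if (is.null(cols)) cols <- names(data)[vapply(data, is.numeric, logical(1))]
  purrr::map_dfr(cols, function(cl) {
    v <- data[[cl]]
    v <- v[is.finite(v)]
    n <- length(v)
    if (n < 3) stop_isokrig(sprintf("Column '%s': need n >= 3.", cl), "sample_size")
    s <- stats::sd(v)
    constant <- s == 0
    sw <- if (!constant && n >= 3 && n <= 5000) {
      stats::shapiro.test(v)
    } else {
      NULL
    }
    tibble::tibble(
      variable = cl, n = n, mean = mean(v), sd = s, min = min(v), max = max(v),
      skewness = if (constant) NA_real_ else skewness_adj(v),
      kurtosis_excess = if (constant) NA_real_ else kurtosis_excess(v),
      shapiro_w = if (is.null(sw)) NA_real_ else unname(sw$statistic),
      shapiro_p = if (is.null(sw)) NA_real_ else sw$p.value,
      normality_defined = !constant
    )
  })
}

# Adjusted Fisher-Pearson skewness: G1 = g1 * sqrt(n(n-1))/(n-2)
skewness_adj <- function(v) {
  n <- length(v)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  m3 <- mean((v - m)^3)
  g1 <- m3 / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

# Excess kurtosis: m4/m2^2 - 3 (moment definition)
kurtosis_excess <- function(v) {
  m <- mean(v)
  m2 <- mean((v - m)^2)
  m4 <- mean((v - m)^4)
  m4 / m2^2 - 3
}

#' Pearson correlation screen of isotopes against candidate covariates
#'
#' Computes Pearson r with two-sided t-test p-values for every
#' isotope x covariate pair. Projected `x`/`y` coordinates can be included
#' among the covariates to probe longitude/latitude effects. Significance
#' stars follow the usual 0.05 / 0.01 / 0.001 coding; `r_display` blanks
#' out values not significant at 0.05, mirroring the usual rendered table.
#'
#' @param sites Data frame.
#' @param isotope_cols,covariate_cols Character vectors of column names.
#' @return Tibble with `isotope`, `covariate`, `r`, `p`, `n`, `stars`,
#'   `r_display`.
#' @export
pearson_screen <- function(sites, isotope_cols, covariate_cols) {
  check_site_table(sites, c(isotope_cols, covariate_cols))
  grid <- tidyr::expand_grid(isotope = isotope_cols, covariate = covariate_cols)
  purrr::pmap_dfr(grid, function(isotope, covariate) {
    a <- sites[[isotope]]; b <- sites[[covariate]]
    ok <- is.finite(a) & is.finite(b)
    n <- sum(ok)
    if (n < 4) stop_isokrig("Need >= 4 complete pairs.", "sample_size")
    if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
      return(tibble::tibble(isotope = isotope, covariate = covariate,
                            r = NA_real_, p = NA_real_, n = n,
                            stars = "", r_display = NA_real_))
    }
    ct <- stats::cor.test(a[ok], b[ok], method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
    stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
    tibble::tibble(
      isotope = isotope, covariate = covariate, r = r, p = p, n = n,
      stars = stars, r_display = if (p < 0.05) r else NA_real_
    )
  })
}

#' Rank candidate covariates by regression AIC
#'
#' Fits the simple linear regression of the isotope on each candidate
#' covariate and reports `AIC = n log(RSS/n) + 2k` with `k = 3` (intercept,
#' slope, error variance). Only AIC differences matter, so the constant
#' terms of the Gaussian likelihood are dropped. The covariate with the
#' lowest AIC is the cokriging covariate of choice.
#'
#' @param sites Data frame.
#' @param isotope_col Response column name.
#' @param covariate_cols Candidate covariate column names.
#' @return Tibble ordered by AIC: `covariate`, `aic`, `rss`, `slope`, `n`,
#'   `degenerate` (TRUE when the fit is numerically perfect and the AIC is
#'   floored).
#' @export
covariate_aic <- function(sites, isotope_col, covariate_cols) {
  check_site_table(sites, c(isotope_col, covariate_cols))
  out <- purrr::map_dfr(covariate_cols, function(cv) {
    a <- sites[[isotope_col]]; b <- sites[[cv]]
    ok <- is.finite(a) & is.finite(b)
    n <- sum(ok)
    if (n < 4) stop_isokrig("Need >= 4 complete pairs.", "sample_size")
    if (stats::sd(b[ok]) == 0) stop_isokrig(sprintf("Covariate '%s' is constant.", cv),
                                            "regression_error")
    fit <- stats::lm(a[ok] ~ b[ok])
    rss <- sum(stats::resid(fit)^2)
    degenerate <- rss < n * 1e-12 * stats::var(a[ok])
    rss_floor <- max(rss, n * 1e-300)
    tibble::tibble(
      covariate = cv,
      aic = n * log(rss_floor / n) + 2 * 3,
      rss = rss,
      slope = unname(stats::coef(fit)[2]),
      n = n,
      degenerate = degenerate
    )
  })
  dplyr::arrange(out, .data$aic)
}

#' Moran's I spatial autocorrelation with a permutation test
#'
#' `I = (n / S0) * sum_ij w_ij (z_i - zbar)(z_j - zbar) / sum_i (z_i - zbar)^2`
#' with expectation `-1/(n-1)` under spatial randomness. Weights default to
#' row-standardized inverse Euclidean distance, optionally truncated at
#' `cutoff`. Significance is assessed by random permutation of the values
#' over the locations (one-sided, greater).
#'
#' @param sites Data frame with `x`, `y`.
#' @param values Numeric vector or column name.
#' @param cutoff Optional distance (m) beyond which weights are zero.
#' @param row_standardize Row-standardize the weight matrix (default TRUE).
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional RNG seed for the permutation test.
#' @return Tibble with `moran_i`, `expected`, `p_perm`, `n`, `n_perm`.
#' @export
morans_i <- function(sites, values, cutoff = NULL, row_standardize = TRUE,
                     n_perm = 999, seed = NULL) {
  check_site_table(sites)
  z <- resolve_values(sites, values)
  n <- length(z)
  if (n < 4) stop_isokrig("Need at least 4 sites.", "input_error")
  if (stats::sd(z) == 0) stop_isokrig("Values are constant.", "input_error")
  D <- dist_matrix(sites$x, sites$y)
  W <- 1 / D
  diag(W) <- 0
  W[!is.finite(W)] <- 0
  if (!is.null(cutoff)) W[D > cutoff] <- 0
  if (all(W == 0)) stop_isokrig("All spatial weights are zero.", "weights_error")
  if (row_standardize) {
    rs <- rowSums(W)
    rs[rs == 0] <- 1
    W <- W / rs
  }
  s0 <- sum(W)
  stat <- function(v) {
    d <- v - mean(v)
    (n / s0) * drop(crossprod(d, W %*% d)) / sum(d^2)
  }
  i_obs <- stat(z)
  p <- with_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(k) stat(sample(z)), 0)
    (1 + sum(perm >= i_obs)) / (n_perm + 1)
  })
  tibble::tibble(
    moran_i = i_obs, expected = -1 / (n - 1), p_perm = p,
    n = n, n_perm = n_perm
  )
}
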