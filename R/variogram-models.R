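#' Construct a parametric variogram model
#'
#' Supported families: `"spherical"`, `"exponential"`, `"linear"` (unbounded,
#' slope parameter), and `"matern_stein"` (Matern with the Stein
#' parameterization, shape `kappa`; reduces to the exponential model at
#' `kappa = 0.5` and approaches a Gaussian model as `kappa` grows).
#'
#' @param family One of `"spherical"`, `"exponential"`, `"linear"`,
#'   `"matern_stein"`.
#' @param nugget Nugget variance c0 (>= 0), squared permil.
#' @param psill Partial sill c (>= 0) for bounded families; ignored for
#'   `"linear"`.
#' @param range Range parameter a (m, > 0); ignored for `"linear"`.
#' @param kappa Matern shape (> 0), `"matern_stein"` only.
#' @param slope Slope b (squared permil per metre), `"linear"` only.
#' @param rss,aic,converged Optional fit diagnostics.
#' @return An object of class `vgm_model`.
#' @examples
#' m <- vgm_model("spherical", nugget = 0, psill = 1, range = 30000)
#' model_gamma(m, 15000) # 0.6875
#' @export
vgm_model <- function(family, nugget = 0, psill = NA_real_, range = NA_real_,
                      kappa = NA_real_, slope = NA_real_,
                      rss = NA_real_, aic = NA_real_, converged = NA) {
  family <- match.arg(family, c("spherical", "exponential", "linear", "matern_stein"))
  if (nugget < 0) stop_isokrig("nugget must be >= 0", "parameter_error")
  if (family == "linear") {
    if (is.na(slope) || slope < 0) stop_isokrig("linear model needs slope >= 0", "parameter_error")
  } else {
    if (is.na(psill) || psill < 0) stop_isokrig("psill must be >= 0", "parameter_error")
    if (is.na(range) || range <= 0) stop_isokrig("range must be > 0", "parameter_error")
    if (family == "matern_stein" && (is.na(kappa) || kappa <= 0)) {
      stop_isokrig("matern_stein needs kappa > 0", "parameter_error")
    }
  }
  structure(
    list(family = family, nugget = nugget, psill = psill, range = range,
         kappa = kappa, slope = slope, rss = rss, aic = aic, converged = converged),
    class = "vgm_model"
  )
}

#' @export
print.vgm_model <- function(x, ...) {
  pars <- switch(x$family,
    linear = sprintf("c0 = %.4g, slope = %.4g", x$nugget, x$slope),
    matern_stein = sprintf("c0 = %.4g, c = %.4g, a = %.4g m, kappa = %.3g",
                           x$nugget, x$psill, x$range, x$kappa),
    sprintf("c0 = %.4g, c = %.4g, a = %.4g m", x$nugget, x$psill, x$range)
  )
  cat(sprintf("<vgm_model> %s: %s", x$family, pars))
  if (is.finite(x$rss)) cat(sprintf("  [RSS %.4g, AIC %.4g]", x$rss, x$aic))
  cat("\n")
  invisible(x)
}

#' Evaluate a variogram model
#'
#' Returns the theoretical semivariance at lag `h`. `gamma(0) = 0`; the
#' nugget is the limit from the right, so any `h > 0` includes the full
#' nugget.
#'
#' @param model A `vgm_model`.
#' @param h Lag distance(s), metres, `>= 0`.
#' @return Semivariance, squared permil.
#' @export
model_gamma <- function(model, h) {
  stopifnot(inherits(model, "vgm_model"))
  if (any(h < 0)) stop_isokrig("Lag distances must be >= 0.", "domain_error")
  g <- unit_gamma(model$family, h, model$range, model$kappa)
  structural <- if (model$family == "linear") model$slope * h else model$psill * g
  out <- ifelse(h > 0, model$nugget + structural, 0)
  as.numeric(out)
}

# Unit-sill structural component (0 at h = 0, -> 1 as h -> Inf for bounded
# families; h itself for linear, scaled by the caller).
unit_gamma <- function(family, h, range = NA, kappa = NA) {
  switch(family,
    spherical = ifelse(h >= range, 1, 1.5 * h / range - 0.5 * (h / range)^3),
    exponential = 1 - exp(-h / range),
    linear = h,
    matern_stein = matern_stein_gamma(h, range, kappa),
    nugget = as.numeric(h > 0)
  )
}

# Matern correlation, Stein parameterization:
#   rho(h) = 2^(1-kappa)/Gamma(kappa) * (h*sqrt(2*kappa)/a)^kappa * K_kappa(...)
matern_stein_gamma <- function(h, range, kappa) {
  u <- h * sqrt(2 * kappa) / range
  out <- numeric(length(u))
  pos <- u > 0
  # besselK underflows for large u; correlation is ~0 there anyway
  uu <- pmin(u[pos], 600)
  rho <- (2^(1 - kappa) / gamma(kappa)) * uu^kappa * besselK(uu, kappa)
  rho[!is.finite(rho)] <- 0
  out[pos] <- 1 - pmin(pmax(rho, 0), 1)
  out
}

# Stationary covariance implied by a bounded-family model (sill - gamma);
# the linear family has no sill, so a reference sill at `ref_dist` is used
# (valid as an intrinsic-process device on a bounded domain).
model_covariance <- function(model, h, ref_dist = NULL) {
  if (model$family == "linear") {
    if (is.null(ref_dist)) stop_isokrig("linear covariance needs ref_dist", "parameter_error")
    sill <- model$nugget + model$slope * ref_dist
  } else {
    sill <- model$nugget + model$psill
  }
  sill - model_gamma(model, h)
}

n_params <- function(model_or_family, kappa_fitted = TRUE) {
  fam <- if (inherits(model_or_family, "vgm_model")) model_or_family$family else model_or_family
  switch(fam,
    linear = 2L,                       # nugget, slope
    matern_stein = if (kappa_fitted) 4L else 3L,
    3L                                 # nugget, psill, range
  )
}

#' Fit a variogram model to an empirical variogram by weighted least squares
#'
#' Minimizes `sum_h w_h (gamma_hat(h) - gamma(h; theta))^2`. Default weights
#' are `N(h)/h^2` (pair count over squared lag); alternatives `"np"`
#' (`N(h)`), `"cressie"` (`N(h)/gamma(h; theta)^2`) and `"equal"` are
#' available. Multistart initial values are data-driven: nugget from the
#' first bin, sill from the empirical maximum (or a supplied sample
#' variance), range from fractions of the maximum lag. Reported `rss` is the
#' unweighted residual sum of squares over bins and
#' `aic = m log(RSS/m) + 2k` with `m` bins and `k` free parameters.
#'
#' @param emp An `empirical_variogram` (see [empirical_variogram()]).
#' @param family Model family (see [vgm_model()]).
#' @param init Optional named list of starting values
#'   (`nugget`, `psill`, `range`, `kappa`, `slope`).
#' @param weights Weighting scheme: `"np_h2"` (default), `"np"`, `"cressie"`,
#'   `"equal"`.
#' @param sill_hint Optional sample variance used as the sill initializer
#'   (the classical definition of the sill as the variable's variance).
#' @return A fitted `vgm_model` with `rss`, `aic`, `converged` filled in.
#' @export
fit_variogram_model <- function(emp, family, init = NULL,
                                weights = c("np_h2", "np", "cressie", "equal"),
                                sill_hint = NULL) {
  weights <- match.arg(weights)
  family <- match.arg(family, c("spherical", "exponential", "linear", "matern_stein"))
  emp <- emp[is.finite(emp$gamma) & emp$np > 0, , drop = FALSE]
  if (nrow(emp) < 4) stop_isokrig("Need >= 4 non-empty lag bins to fit.", "fit_error")
  h <- emp$lag; g <- emp$gamma; np <- emp$np
  w <- switch(weights,
    np_h2 = np / h^2,
    np = np,
    cressie = np, # refined inside the objective
    equal = rep(1, length(h))
  )
  w <- w / sum(w)

  sill0 <- sill_hint %||% max(g)
  if (!is.finite(sill0) || sill0 <= 0) sill0 <- max(g, 1e-12)
  nug0 <- max(min(g[1], sill0), 0)
  hmax <- max(h)

  # optimize in scaled units (sills / sill0, range / hmax) so nlminb sees
  # parameters of comparable magnitude; par = (nugget, psill, range[, kappa])
  obj_factory <- function(fam) {
    function(par_s) {
      par <- c(par_s[1] * sill0, par_s[2] * sill0, par_s[3] * hmax, par_s[-(1:3)])
      m <- par_to_model(fam, par)
      gg <- model_gamma(m, h)
      wi <- if (weights == "cressie") np / pmax(gg, 1e-12)^2 else w
      sum(wi * (g - gg)^2) / sill0^2
    }
  }
  unscale <- function(par_s) {
    c(par_s[1] * sill0, par_s[2] * sill0, par_s[3] * hmax, par_s[-(1:3)])
  }

  if (family == "linear") {
    # Linear in (nugget, slope): closed-form WLS with nonnegativity clamp.
    fit <- wls_line_nonneg(h, g, w)
    m <- vgm_model("linear", nugget = fit$intercept, slope = fit$slope)
    m$converged <- TRUE
  } else if (family == "matern_stein") {
    kappas <- exp(seq(log(0.05), log(10), length.out = 13))
    best <- NULL
    for (k in kappas) {
      r <- multistart_fit(obj_factory("matern_stein_fixk"), nug0 / sill0,
                          extra = k, init = init, sill0 = sill0, hmax = hmax)
      if (is.null(best) || r$objective < best$objective) best <- r
    }
    # refine with kappa free
    refine <- tryCatch(
      stats::nlminb(
        start = best$par_s,
        objective = obj_factory("matern_stein"),
        lower = c(0, 0, 1e-4, 0.05),
        upper = c(Inf, Inf, 20, 10),
        control = list(eval.max = 500, iter.max = 300)
      ),
      error = function(e) NULL
    )
    use <- if (!is.null(refine) && refine$objective <= best$objective) {
      list(par = refine$par, conv = TRUE)
    } else {
      list(par = best$par_s, conv = best$converged)
    }
    m <- par_to_model("matern_stein", unscale(use$par))
    m$converged <- use$conv
  } else {
    r <- multistart_fit(obj_factory(family), nug0 / sill0, init = init,
                        sill0 = sill0, hmax = hmax)
    m <- par_to_model(family, unscale(r$par_s))
    m$converged <- r$converged
  }

  res <- g - model_gamma(m, h)
  m$rss <- sum(res^2)
  k <- n_params(family)
  mbins <- length(h)
  rss_floor <- max(m$rss, mbins * 1e-300)
  m$aic <- mbins * log(rss_floor / mbins) + 2 * k
  m$weights <- weights
  m
}

# par layouts: bounded: (nugget, psill, range[, kappa]); "matern_stein_fixk"
# carries kappa through the closure via attr.
par_to_model <- function(fam, par) {
  if (fam == "linear") {
    vgm_model("linear", nugget = max(par[1], 0), slope = max(par[2], 0))
  } else if (fam == "matern_stein" || fam == "matern_stein_fixk") {
    vgm_model("matern_stein", nugget = max(par[1], 0), psill = max(par[2], 0),
              range = max(par[3], 1e-12), kappa = min(max(par[4], 0.05), 10))
  } else {
    vgm_model(fam, nugget = max(par[1], 0), psill = max(par[2], 0),
              range = max(par[3], 1e-12))
  }
}

# Multistart nlminb in scaled parameter space: par_s = (nugget/sill0,
# psill/sill0, range/hmax[, kappa]).
multistart_fit <- function(obj, nug0_s, extra = NULL, init = NULL,
                           sill0 = 1, hmax = 1) {
  starts <- list(
    c(nug0_s, max(1 - nug0_s, 0.1), 1 / 3),
    c(0, 1, 1 / 3),
    c(nug0_s / 2, 1, 1 / 2),
    c(nug0_s, max(1 - nug0_s, 0.1), 2 / 3),
    c(0.25, 0.75, 1 / 6),
    c(0, 1, 1)
  )
  if (!is.null(init)) {
    starts <- c(list(c((init$nugget %||% (nug0_s * sill0)) / sill0,
                       (init$psill %||% sill0) / sill0,
                       (init$range %||% (hmax / 3)) / hmax)), starts)
  }
  best <- NULL
  for (s in starts) {
    par <- if (!is.null(extra)) c(s, extra) else s
    lower <- c(0, 0, 1e-4)
    upper <- c(Inf, Inf, 20)
    if (!is.null(extra)) { lower <- c(lower, extra); upper <- c(upper, extra) }
    r <- tryCatch(
      stats::nlminb(start = par, objective = obj, lower = lower, upper = upper,
                    control = list(eval.max = 500, iter.max = 300)),
      error = function(e) NULL
    )
    if (is.null(r)) next
    if (is.null(best) || r$objective < best$objective) {
      best <- list(objective = r$objective, par_s = r$par,
                   converged = r$convergence == 0)
    }
  }
  if (is.null(best)) stop_isokrig("Variogram fit failed from every start.", "fit_error")
  best
}

# Weighted least squares line with nonnegative intercept and slope.
wls_line_nonneg <- function(h, g, w) {
  fit2 <- function(fix_int0) {
    if (fix_int0) {
      b <- sum(w * h * g) / sum(w * h^2)
      list(intercept = 0, slope = max(b, 0))
    } else {
      X <- cbind(1, h)
      W <- diag(w)
      beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% g)
      list(intercept = beta[1], slope = beta[2])
    }
  }
  f <- fit2(FALSE)
  if (f$intercept < 0 || f$slope < 0) {
    cand <- list(
      fit2(TRUE),
      list(intercept = max(sum(w * g) / sum(w), 0), slope = 0)
    )
    sse <- vapply(cand, function(cc) sum(w * (g - cc$intercept - cc$slope * h)^2), 0)
    f <- cand[[which.min(sse)]]
    f$intercept <- max(f$intercept, 0); f$slope <- max(f$slope, 0)
  }
  f
}

#' Select the best variogram model among fitted candidates
#'
#' Picks the candidate with the lowest AIC; ties (within `1e-9`) broken by
#' lower RSS, then by fewer parameters, then input order.
#'
#' @param candidates List of fitted `vgm_model` objects.
#' @return The selected `vgm_model`.
#' @export
select_model <- function(candidates) {
  if (inherits(candidates, "vgm_model")) candidates <- list(candidates)
  ok <- vapply(candidates, function(m) isTRUE(m$converged), logical(1))
  if (!any(ok)) stop_isokrig("No converged candidate model.", "selection_error")
  cand <- candidates[ok]
  aic <- vapply(cand, function(m) m$aic, 0)
  rss <- vapply(cand, function(m) m$rss, 0)
  k <- vapply(cand, n_params, 0L)
  ord <- order(round(aic / 1e-9) * 1e-9, rss, k)
  cand[[ord[1]]]
}
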