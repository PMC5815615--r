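test_that("empirical variogram equals the all-pairs brute force", {
  # hand case: two points, distance 10, values 0 and 2 -> gamma = 2
  two <- data.frame(x = c(0, 10), y = c(0, 0))
  ev <- empirical_variogram(two, c(0, 2), lag_width = 25, max_dist = 25) |>
    suppressWarnings()
  expect_equal(ev$gamma, 2)
  expect_equal(ev$np, 1L)
  # constant field -> flat zero
  set.seed(1)
  s5 <- random_sites(12, seed = 2, width = 100)
  evc <- empirical_variogram(s5, rep(3.3, 12), lag_width = 20, max_dist = 120)
  expect_true(all(evc$gamma == 0))
  # brute-force equality on random instances up to n = 30
  for (n in c(5, 17, 30)) {
    s <- random_sites(n, seed = n, width = 5000)
    set.seed(n + 1)
    z <- rnorm(n)
    ev <- suppressWarnings(empirical_variogram(s, z, lag_width = 800, max_dist = 4000))
    bf <- oracle_variogram(s, z, lag_width = 800, max_dist = 4000)
    expect_equal(ev$lag, unname(bf$lag))
    expect_equal(ev$gamma, unname(bf$gamma))
    expect_equal(ev$np, bf$np)
  }
})

test_that("directional variograms partition pairs by bearing", {
  # field varying only with y: N-S pairs carry the variance
  set.seed(3)
  s <- data.frame(x = runif(80, 0, 1e4), y = runif(80, 0, 1e4))
  z <- s$y / 1e3
  ns <- empirical_variogram(s, z, lag_width = 2000, max_dist = 8000,
                            direction = 0, tol = 20)
  ew <- empirical_variogram(s, z, lag_width = 2000, max_dist = 8000,
                            direction = 90, tol = 20)
  expect_gt(mean(ns$gamma), 5 * mean(ew$gamma))
})

test_that("variogram map is centro-symmetric and aligns with anisotropy", {
  set.seed(4)
  s <- data.frame(x = runif(120, 0, 1e4), y = runif(120, 0, 1e4))
  vm <- variogram_map(s, s$y / 1e3, cell = 2500)
  # map(delta) = map(-delta)
  key <- paste(vm$dx, vm$dy)
  mirror <- paste(-vm$dx, -vm$dy)
  expect_true(all(mirror %in% key))
  expect_equal(vm$gamma[match(mirror, key)], vm$gamma)
  # high-gamma axis along N-S for a y-only field
  ns_cells <- vm$gamma[abs(vm$dx) <= 2500 & abs(vm$dy) >= 5000]
  ew_cells <- vm$gamma[abs(vm$dy) <= 2500 & abs(vm$dx) >= 5000]
  expect_gt(mean(ns_cells), 3 * mean(ew_cells))
})

test_that("model_gamma matches the closed forms of every family", {
  sph <- vgm_model("spherical", nugget = 0, psill = 1, range = 30000)
  expect_equal(model_gamma(sph, 15000), 0.6875)
  expect_equal(model_gamma(sph, 30000), 1)
  expect_equal(model_gamma(sph, 60000), 1)
  expon <- vgm_model("exponential", nugget = 0.5, psill = 2, range = 1e4)
  expect_equal(model_gamma(expon, 1e4), 0.5 + 2 * (1 - exp(-1)))
  lin <- vgm_model("linear", nugget = 0.2, slope = 1e-4)
  expect_equal(model_gamma(lin, 5000), 0.2 + 0.5)
  # Matern-Stein at kappa = 0.5 is the exponential model (Bessel K_{1/2})
  ms <- vgm_model("matern_stein", nugget = 0, psill = 1, range = 7000, kappa = 0.5)
  me <- vgm_model("exponential", nugget = 0, psill = 1, range = 7000)
  hs <- seq(0, 35000, by = 111)
  expect_lt(max(abs(model_gamma(ms, hs) - model_gamma(me, hs))), 1e-9)
  # nugget is the limit from the right; gamma(0) = 0
  for (m in list(sph, expon, lin, ms)) {
    expect_equal(model_gamma(m, 0), 0)
    expect_equal(model_gamma(m, 1e-9), m$nugget, tolerance = 1e-6)
  }
  expect_error(model_gamma(sph, -1), class = "isokrig_domain_error")
})

test_that("model_gamma is monotone non-decreasing over [0, 3a]", {
  models <- list(
    vgm_model("spherical", 0.1, 1, 20000),
    vgm_model("exponential", 0, 2, 15000),
    vgm_model("linear", 0.3, slope = 1e-5),
    vgm_model("matern_stein", 0.2, 1.5, 25000, kappa = 0.3),
    vgm_model("matern_stein", 0, 1, 25000, kappa = 3)
  )
  hs <- seq(0, 75000, length.out = 400)
  for (m in models) {
    g <- model_gamma(m, hs)
    expect_true(all(diff(g) >= -1e-10))
  }
})

test_that("WLS fitting recovers exact curves and is scale-equivariant", {
  true <- vgm_model("spherical", nugget = 0.2, psill = 1, range = 30000)
  hs <- seq(1250, 40000, by = 2500)
  emp <- tibble::tibble(lag = hs, gamma = model_gamma(true, hs), np = 100L)
  class(emp) <- c("empirical_variogram", class(emp))
  fit <- fit_variogram_model(emp, "spherical")
  expect_equal(fit$nugget, 0.2, tolerance = 1e-5)
  expect_equal(fit$psill, 1, tolerance = 1e-5)
  expect_equal(fit$range, 30000, tolerance = 1e-3)
  # scale equivariance: values * s => c0, c * s^2, range unchanged
  emp2 <- emp; emp2$gamma <- emp$gamma * 9
  fit2 <- fit_variogram_model(emp2, "spherical")
  expect_equal(fit2$nugget, 9 * fit$nugget, tolerance = 1e-5)
  expect_equal(fit2$psill, 9 * fit$psill, tolerance = 1e-5)
  expect_equal(fit2$range, fit$range, tolerance = 1e-5)
  # spherical wins the family competition on its own exact curve
  fits <- lapply(c("spherical", "exponential", "linear", "matern_stein"),
                 function(f) fit_variogram_model(emp, f))
  rss <- vapply(fits, function(m) m$rss, 0)
  expect_equal(which.min(rss), 1L)
})

test_that("fitted range is recovered from simulated fields", {
  # parameter recovery at moderate replication (the acceptance suite runs
  # the full-scale version)
  true <- vgm_model("spherical", nugget = 0, psill = 1, range = 30000)
  sites <- sample_sites(300, seed = 1)
  fs <- field_spec(true)
  ranges <- vapply(1:15, function(r) {
    z <- simulate_grf(sites, fs, seed = 100 + r)
    emp <- empirical_variogram(sites, z, lag_width = 2500, max_dist = 60000)
    fit_variogram_model(emp, "spherical", sill_hint = var(z))$range
  }, 0)
  expect_lt(abs(median(ranges) - 30000) / 30000, 0.2)
})

test_that("model selection prefers low AIC with RSS tie-breaking", {
  a <- vgm_model("spherical", 0, 1, 1e4, rss = 1, aic = 10, converged = TRUE)
  b <- vgm_model("exponential", 0, 1, 1e4, rss = 0.5, aic = 10, converged = TRUE)
  cc <- vgm_model("spherical", 0, 1, 1e4, rss = 2, aic = 12, converged = TRUE)
  expect_identical(select_model(list(a, b, cc))$family, "exponential")
  expect_identical(select_model(list(a))$family, "spherical")
  bad <- vgm_model("spherical", 0, 1, 1e4, converged = FALSE)
  expect_error(select_model(list(bad)), class = "isokrig_selection_error")
})

test_that("trend fitting reproduces polynomial surfaces exactly", {
  set.seed(12)
  s <- data.frame(x = runif(40, 0, 1e5), y = runif(40, 0, 1e5))
  z <- 3 + 2e-4 * s$x
  tr <- fit_trend(s, z, order = 1)
  expect_equal(unname(tr$coefficients_raw), c(3, 2e-4, 0), tolerance = 1e-8)
  expect_true(all(abs(tr$residuals) < 1e-8))
  zq <- 1 + 1e-4 * s$x - 2e-4 * s$y + 1e-9 * s$x^2 - 3e-9 * s$x * s$y + 2e-9 * s$y^2
  tr2 <- fit_trend(s, zq, order = 2)
  expect_true(all(abs(tr2$residuals) < 1e-8))
  expect_equal(predict(tr2, data.frame(x = 5e4, y = 2e4)),
               1 + 1e-4 * 5e4 - 2e-4 * 2e4 + 1e-9 * 25e8 - 3e-9 * 1e9 + 2e-9 * 4e8,
               tolerance = 1e-8)
})

test_that("detrending lowers the apparent sill growth at large lags", {
  sites <- sample_sites(151, seed = 77)
  base <- simulate_grf(sites, field_spec(vgm_model("spherical", 0.1, 0.5, 20000)),
                       seed = 8)
  z <- base + 5e-5 * sites$y # strong latitude trend
  raw <- empirical_variogram(sites, z, lag_width = 2500)
  tr <- fit_trend(sites, z, order = 1)
  det <- empirical_variogram(sites, tr$residuals, lag_width = 2500)
  top <- raw$lag > max(raw$lag) * 0.6
  expect_gt(mean(raw$gamma[top]), mean(det$gamma[det$lag > max(det$lag) * 0.6]))
})

test_that("cross-variograms reduce to direct variograms in degenerate cases", {
  sites <- sample_sites(60, seed = 5)
  z <- simulate_grf(sites, field_spec(vgm_model("spherical", 0.1, 1, 25000)), seed = 3)
  direct <- empirical_variogram(sites, z, lag_width = 5000)
  same <- cross_variogram(sites, z, z, lag_width = 5000)
  expect_equal(same$gamma, direct$gamma, tolerance = 1e-12)
  neg <- cross_variogram(sites, z, -z, lag_width = 5000)
  expect_equal(neg$gamma, -direct$gamma, tolerance = 1e-12)
  expect_error(cross_variogram(sites, z, z[-1]), class = "isokrig_alignment_error")
})

test_that("cross-variogram of independent fields averages to zero", {
  sites <- sample_sites(60, seed = 6)
  fs <- field_spec(vgm_model("spherical", 0, 1, 25000))
  means <- vapply(1:60, function(r) {
    a <- simulate_grf(sites, fs, seed = 2000 + r)
    b <- simulate_grf(sites, fs, seed = 9000 + r)
    mean(cross_variogram(sites, a, b, lag_width = 5000)$gamma)
  }, 0)
  expect_lt(abs(mean(means)), 2 * sd(means) / sqrt(length(means)) + 0.05)
})
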