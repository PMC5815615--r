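test_that("site sampling is uniform-in-polygon and seed-deterministic", {
  poly <- trentino_polygon()
  s <- sample_sites(151, poly, seed = 1)
  expect_equal(nrow(s), 151)
  expect_true(all(points_inside <- isokrig:::points_in_polygon(s$x, s$y, poly$x, poly$y)))
  # unit square, single point
  sq <- data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  one <- sample_sites(1, sq, seed = 3)
  expect_true(one$x >= 0 && one$x <= 1 && one$y >= 0 && one$y <= 1)
  expect_identical(sample_sites(40, poly, seed = 9), sample_sites(40, poly, seed = 9))
  expect_error(sample_sites(5, data.frame(x = c(0, 1, 2), y = c(0, 0, 0)), seed = 1),
               class = "isokrig_domain_error")
})

test_that("degenerate field specs reproduce their trend exactly", {
  s <- sample_sites(20, seed = 2)
  fs <- field_spec(vgm_model("spherical", nugget = 0, psill = 0, range = 1000),
                   trend_coeffs = c(`(Intercept)` = -80))
  expect_equal(simulate_grf(s, fs, seed = 1), rep(-80, 20))
  fs2 <- field_spec(vgm_model("spherical", 0, 0, 1000),
                    trend_coeffs = c(`(Intercept)` = 2, x = 1e-5))
  expect_equal(simulate_grf(s, fs2, seed = 1), 2 + 1e-5 * s$x)
  expect_identical(simulate_grf(s, field_spec(vgm_model("spherical", 0.5, 1, 2e4)), 7),
                   simulate_grf(s, field_spec(vgm_model("spherical", 0.5, 1, 2e4)), 7))
})

test_that("simulated fields honour the generating variogram (Monte Carlo)", {
  # spherical: mean empirical semivariance at a/2 near the closed-form 0.6875
  sites <- sample_sites(400, seed = 30)
  m <- vgm_model("spherical", nugget = 0, psill = 1, range = 30000)
  fs <- field_spec(m)
  gam_half <- vapply(1:60, function(r) {
    z <- simulate_grf(sites, fs, seed = 400 + r)
    ev <- empirical_variogram(sites, z, lag_width = 2500, max_dist = 40000)
    ev$gamma[which.min(abs(ev$lag - 15000))]
  }, 0)
  expect_lt(abs(mean(gam_half) - 0.6875) / 0.6875, 0.1)
  # marginal variance near the sill
  vars <- vapply(1:60, function(r)
    var(simulate_grf(sites, fs, seed = 400 + r)), 0)
  expect_lt(abs(mean(vars) - 1), 0.12)
})

test_that("pure-nugget fields are white noise with unit variance", {
  sites <- sample_sites(300, seed = 31)
  fs <- field_spec(vgm_model("spherical", nugget = 1, psill = 0, range = 1000))
  stats <- vapply(1:60, function(r) {
    z <- simulate_grf(sites, fs, seed = 800 + r)
    ev <- empirical_variogram(sites, z, lag_width = 10000, max_dist = 60000)
    c(var(z), mean(ev$gamma))
  }, c(0, 0))
  expect_equal(mean(stats[1, ]), 1, tolerance = 0.1)
  expect_equal(mean(stats[2, ]), 1, tolerance = 0.1)
})

test_that("the Alpine-like dataset reproduces the study's envelopes", {
  ds <- make_trentino_like(seed = 1)
  st <- ds$sites
  expect_equal(nrow(st), 151)
  expect_equal(sum(st$n_trees), 755)
  expect_equal(range(st$altitude), c(547, 1974))
  expect_true(all(c("d18O_2013", "d18O_2014", "d2H_2013", "d2H_2014") %in% names(st)))
  # 20-seed sweeps: guard bands and correlation signs
  for (seed in 1:20) {
    sti <- make_trentino_like(seed = seed)$sites
    expect_true(all(sti$d2H_2013 >= -120 & sti$d2H_2013 <= -40))
    expect_true(all(sti$d2H_2014 >= -120 & sti$d2H_2014 <= -40))
    expect_lt(cor(sti$d18O_2014, sti$altitude), 0)
    expect_lt(cor(sti$d2H_2013, sti$altitude), 0)
  }
  expect_identical(make_trentino_like(seed = 5)$sites, make_trentino_like(seed = 5)$sites)
})

test_that("the synthetic fields carry a 20-70 km autocorrelation range", {
  # single-seed range estimates are noisy under the dominant nugget, so the
  # check is on the median fitted range across seeds
  rngs <- vapply(1:8, function(s) {
    st <- make_trentino_like(seed = s)$sites
    tr <- fit_trend(st, st$d2H_2013, order = 1)
    emp <- empirical_variogram(st, tr$residuals, lag_width = 2500)
    fit_variogram_model(emp, "spherical", sill_hint = var(tr$residuals))$range
  }, 0)
  expect_gt(median(rngs), 10000)
  expect_lt(median(rngs), 90000)
  # and the generating truth itself sits in the published 20-70 km window
  truth <- make_trentino_like(seed = 1)$truth
  for (sp in truth) {
    expect_gte(sp$range, 20000)
    expect_lte(sp$range, 70000)
  }
})
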