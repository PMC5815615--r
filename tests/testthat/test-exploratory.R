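test_that("descriptive statistics match closed forms and flag degeneracy", {
  d <- data.frame(v = c(1, 2, 3))
  out <- describe_variables(d, "v")
  expect_equal(out$mean, 2)
  expect_equal(out$sd, 1)
  expect_equal(out$skewness, 0)
  # seed-fixed standard-normal sample passes the Shapiro-Wilk gate
  set.seed(500)
  out2 <- describe_variables(data.frame(z = rnorm(500)), "z")
  expect_gt(out2$shapiro_p, 0.05)
  # constant vector: sd zero, normality undefined
  out3 <- describe_variables(data.frame(c = rep(3, 10)), "c")
  expect_equal(out3$sd, 0)
  expect_false(out3$normality_defined)
  expect_error(describe_variables(data.frame(v = c(1, 2)), "v"),
               class = "isokrig_sample_size")
})

test_that("skewness and kurtosis use the adjusted/moment conventions", {
  skip_if_not_installed("e1071")
  set.seed(8)
  v <- rexp(200)
  out <- describe_variables(data.frame(v = v), "v")
  expect_equal(out$skewness, e1071::skewness(v, type = 2), tolerance = 1e-12)
  expect_equal(out$kurtosis_excess, e1071::kurtosis(v, type = 1), tolerance = 1e-12)
})

test_that("pearson_screen reproduces exact correlations and stars", {
  d <- data.frame(a = 1:20, b = -(1:20), c = rnorm(20))
  out <- pearson_screen(d, "a", c("b", "c"))
  expect_equal(out$r[out$covariate == "b"], -1)
  expect_equal(out$stars[out$covariate == "b"], "***")
  # non-significant entries blanked in the display column but kept in r
  set.seed(99)
  d2 <- data.frame(u = rnorm(30), w = rnorm(30))
  o2 <- pearson_screen(d2, "u", "w")
  if (o2$p > 0.05) expect_true(is.na(o2$r_display))
  expect_false(is.na(o2$r))
})

test_that("permuted covariates rarely screen as significant", {
  ds <- make_trentino_like(seed = 4)
  st <- ds$sites
  set.seed(123)
  hits <- vapply(1:300, function(i) {
    st$shuffled <- sample(st$altitude)
    pearson_screen(st, "d18O_2014", "shuffled")$p < 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.10)
})

test_that("covariate AIC ranks the true driver above a shuffled copy", {
  ds <- make_trentino_like(seed = 6)
  st <- ds$sites
  set.seed(42)
  st$shuffled_altitude <- sample(st$altitude)
  out <- covariate_aic(st, "d18O_2014", c("altitude", "shuffled_altitude"))
  expect_equal(out$covariate[1], "altitude")
  # identical covariates tie to 1e-9
  st$altitude2 <- st$altitude
  o2 <- covariate_aic(st, "d18O_2014", c("altitude", "altitude2"))
  expect_equal(o2$aic[1], o2$aic[2], tolerance = 1e-9)
  # AIC ranking invariant under affine rescaling of the covariate
  st$alt_km <- st$altitude / 1000 + 2
  o3 <- covariate_aic(st, "d18O_2014", c("altitude", "alt_km"))
  expect_equal(o3$aic[1], o3$aic[2], tolerance = 1e-9)
  # perfect fit floors the AIC and flags degeneracy
  st$copy <- 2 * st$d18O_2014 + 1
  o4 <- covariate_aic(st, "d18O_2014", "copy")
  expect_true(o4$degenerate)
})

test_that("Moran's I detects a gradient and matches the 4-point brute force", {
  ds <- make_trentino_like(seed = 2, n_sites = 60)
  st <- ds$sites
  out <- morans_i(st, st$x, n_perm = 999, seed = 1)
  expect_gt(out$moran_i, 0)
  expect_lte(out$p_perm, 0.001)
  # 2x2 checkerboard with rook-style (here inverse-distance = equal nearest)
  # weights evaluated against a direct double-sum evaluation of the formula
  sq <- data.frame(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
  z <- c(0, 1, 1, 0)
  W <- 1 / as.matrix(dist(sq)); diag(W) <- 0
  W <- W / rowSums(W)
  zc <- z - mean(z)
  i_direct <- (4 / sum(W)) * sum(W * outer(zc, zc)) / sum(zc^2)
  got <- morans_i(sq, z, n_perm = 99, seed = 1)
  expect_equal(got$moran_i, i_direct, tolerance = 1e-12)
  expect_lt(got$moran_i, got$expected) # strongly negative autocorrelation
  expect_equal(got$expected, -1 / 3)
})

test_that("Moran's I is affine-invariant and calibrated under the null", {
  ds <- make_trentino_like(seed = 9, n_sites = 40)
  st <- ds$sites
  a <- morans_i(st, st$d2H_2013, n_perm = 99, seed = 5)
  b <- morans_i(st, 3 * st$d2H_2013 - 7, n_perm = 99, seed = 5)
  expect_equal(a$moran_i, b$moran_i, tolerance = 1e-10)
  expect_equal(a$p_perm, b$p_perm)
  # permuted values: the null distribution of I is centred at E[I] with
  # roughly Gaussian 2-sigma coverage
  set.seed(31)
  sims <- vapply(1:200, function(i) morans_i(st, sample(st$d2H_2013), n_perm = 9,
                                             seed = i)$moran_i, 0)
  expect_lt(abs(mean(sims) - (-1 / 39)), 2 * sd(sims) / sqrt(length(sims)) + 0.01)
  expect_gte(mean(abs(sims - (-1 / 39)) < 2 * sd(sims)), 0.92)
})
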