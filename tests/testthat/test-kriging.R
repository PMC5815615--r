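test_that("ordinary kriging solves the hand-checkable two-point system", {
  s <- data.frame(x = c(0, 10), y = c(0, 0))
  m <- vgm_model("linear", nugget = 0, slope = 1)
  k <- ok_predict(s, c(0, 2), m, c(5, 0))
  expect_equal(k$prediction, 1)
  expect_equal(k$variance, 5)
  expect_equal(k$weights, c(0.5, 0.5))
  # constant field predicts the constant anywhere
  s2 <- random_sites(12, seed = 1)
  m2 <- vgm_model("spherical", 0.1, 1, 400)
  k2 <- ok_predict(s2, rep(4.2, 12), m2, c(500, 500))
  expect_equal(k2$prediction, 4.2, tolerance = 1e-10)
  expect_gte(k2$variance, 0)
})

test_that("OK and UK match the brute-force GLS BLUP oracle (n <= 10)", {
  set.seed(20)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    s <- random_sites(n, seed = 300 + rep, width = 2000)
    z <- rnorm(n, 10, 2)
    fam <- sample(c("spherical", "exponential"), 1)
    m <- vgm_model(fam, nugget = runif(1, 0, 0.5), psill = runif(1, 0.5, 2),
                   range = runif(1, 300, 3000))
    tgt <- c(runif(1, 0, 2000), runif(1, 0, 2000))
    got <- ok_predict(s, z, m, tgt)
    want <- oracle_blup(s, z, m, tgt)
    expect_equal(got$prediction, want$prediction, tolerance = 1e-8)
    expect_equal(got$variance, want$variance, tolerance = 1e-8)
    if (n >= 6) {
      gotu <- uk_predict(s, z, m, tgt, trend_order = 1)
      wantu <- oracle_blup(s, z, m, tgt, trend_order = 1)
      expect_equal(gotu$prediction, wantu$prediction, tolerance = 1e-8)
      expect_equal(gotu$variance, wantu$variance, tolerance = 1e-8)
    }
  }
})

test_that("cokriging matches the joint-GLS oracle and decouples cleanly", {
  structures <- list(list(family = "nugget"),
                     list(family = "spherical", range = 1500))
  B <- list(matrix(c(0.3, 0.05, 0.05, 0.2), 2),
            matrix(c(1, 0.6, 0.6, 0.9), 2))
  lmc <- lmc_model(structures, B)
  set.seed(33)
  for (rep in 1:10) {
    n <- sample(4:6, 1)
    s <- random_sites(n, seed = 600 + rep, width = 2000)
    z1 <- rnorm(n); z2 <- rnorm(n)
    tgt <- c(runif(1, 0, 2000), runif(1, 0, 2000))
    got <- cok_predict(s, z1, z2, lmc, tgt)
    want <- oracle_cok(s, z1, z2, lmc, tgt)
    expect_equal(got$prediction, want$prediction, tolerance = 1e-8)
    expect_equal(got$variance, want$variance, tolerance = 1e-8)
  }
  # zero cross-structure: cokriging collapses onto ordinary kriging
  B0 <- list(matrix(c(0.3, 0, 0, 0.2), 2), matrix(c(1, 0, 0, 0.9), 2))
  lmc0 <- lmc_model(structures, B0)
  s <- random_sites(8, seed = 44, width = 2000)
  set.seed(44); z1 <- rnorm(8); z2 <- rnorm(8)
  m_ok <- vgm_model("spherical", nugget = 0.3, psill = 1, range = 1500)
  tgt <- c(900, 1100)
  a <- cok_predict(s, z1, z2, lmc0, tgt)
  b <- ok_predict(s, z1, m_ok, tgt)
  expect_equal(a$prediction, b$prediction, tolerance = 1e-8)
  expect_equal(a$variance, b$variance, tolerance = 1e-8)
})

test_that("weight constraints and exactness hold on every solve", {
  set.seed(50)
  s <- random_sites(15, seed = 9, width = 5000)
  z <- rnorm(15, -80, 6)
  m <- vgm_model("spherical", nugget = 2, psill = 20, range = 2500)
  for (tgt in list(c(100, 4900), c(2500, 2500), c(s$x[3], s$y[3]))) {
    for (ord in list(NULL, 1, 2)) {
      k <- if (is.null(ord)) ok_predict(s, z, m, tgt) else uk_predict(s, z, m, tgt, ord)
      expect_equal(sum(k$weights), 1, tolerance = 1e-10)
    }
  }
  # exactness at a data location, zero variance, despite the nugget
  k3 <- ok_predict(s, z, m, c(s$x[3], s$y[3]))
  expect_equal(k3$prediction, z[3], tolerance = 1e-8)
  expect_equal(k3$variance, 0, tolerance = 1e-8)
  # cokriging constraint pair
  structures <- list(list(family = "nugget"), list(family = "spherical", range = 2500))
  lmc <- lmc_model(structures, list(diag(c(2, 1)), matrix(c(20, 8, 8, 5), 2)))
  kc <- cok_predict(s, z, rnorm(15), lmc, c(1000, 1000))
  expect_equal(sum(kc$weights), 1, tolerance = 1e-10)
  expect_equal(sum(kc$weights_covariate), 0, tolerance = 1e-10)
  expect_error(ok_predict(rbind(s, s[1, ]), c(z, z[1]), m, c(0, 0)),
               class = "isokrig_duplicate_sites")
})

test_that("universal kriging reproduces polynomial surfaces exactly", {
  s <- random_sites(20, seed = 7, width = 1000)
  m <- vgm_model("spherical", nugget = 0, psill = 1, range = 500)
  z1 <- 3 + 2e-3 * s$x
  u <- uk_predict(s, z1, m, c(431, 717), trend_order = 1)
  expect_equal(u$prediction, 3 + 2e-3 * 431, tolerance = 1e-6)
  zq <- 1 - 1e-3 * s$x + 2e-3 * s$y + 3e-6 * s$x^2 - 1e-6 * s$x * s$y + 2e-6 * s$y^2
  u2 <- uk_predict(s, zq, m, c(345, 891), trend_order = 2)
  expect_equal(u2$prediction,
               1 - 1e-3 * 345 + 2e-3 * 891 + 3e-6 * 345^2 - 1e-6 * 345 * 891 + 2e-6 * 891^2,
               tolerance = 1e-6)
})

test_that("kriging is translation-invariant and equivariant to value shifts", {
  s <- random_sites(12, seed = 13, width = 3000)
  set.seed(13); z <- rnorm(12)
  m <- vgm_model("exponential", nugget = 0.1, psill = 1, range = 1200)
  tgt <- c(1500, 800)
  base <- ok_predict(s, z, m, tgt)
  shifted <- ok_predict(data.frame(x = s$x + 1e6, y = s$y - 5e5), z, m,
                        tgt + c(1e6, -5e5))
  expect_equal(base$prediction, shifted$prediction, tolerance = 1e-8)
  expect_equal(base$variance, shifted$variance, tolerance = 1e-8)
  plus <- ok_predict(s, z + 7, m, tgt)
  expect_equal(plus$prediction, base$prediction + 7, tolerance = 1e-8)
  uk1 <- uk_predict(s, z + 7, m, tgt, 1)
  expect_equal(uk1$prediction, uk_predict(s, z, m, tgt, 1)$prediction + 7,
               tolerance = 1e-8)
})

test_that("grid prediction honours the mask and shows the edge effect", {
  sites <- sample_sites(40, seed = 15)
  z <- simulate_grf(sites, field_spec(vgm_model("spherical", 0.2, 1, 30000)), seed = 2)
  mask <- polygon_mask(trentino_polygon(), resolution = 10000)
  m <- vgm_model("spherical", 0.2, 1, 30000)
  pg <- predict_grid(sites, z, m, "KriO", mask)
  vals <- pg$prediction$values
  expect_identical(is.na(vals), is.na(mask$values))
  # variance larger at the cell farthest from any site than at the closest
  ct <- tibble::as_tibble(pg$variance)
  ct <- ct[is.finite(ct$value), ]
  dmin <- vapply(seq_len(nrow(ct)), function(i)
    min(sqrt((sites$x - ct$x[i])^2 + (sites$y - ct$y[i])^2)), 0)
  expect_gt(ct$value[which.max(dmin)], ct$value[which.min(dmin)])
  # single-cell mask over a data site: exact, zero variance
  one <- iso_raster(matrix(1, 1, 1), sites$x[1] - 5, sites$y[1] - 5, 10)
  p1 <- predict_grid(sites, z, m, "KriO", one)
  expect_equal(p1$prediction$values[1, 1], z[1], tolerance = 1e-6)
  expect_equal(p1$variance$values[1, 1], 0, tolerance = 1e-6)
  # all-nodata mask warns and returns empty rasters
  expect_warning(pe <- predict_grid(sites, z, m, "KriO",
                                    iso_raster(matrix(NA_real_, 2, 2), 0, 0, 10)),
                 "no valid cells")
  expect_true(all(is.na(pe$prediction$values)))
})
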