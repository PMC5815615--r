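# Independent brute-force oracles. These deliberately avoid the package's
# semivariance-form solvers: kriging is re-derived as a constrained BLUP in
# covariance form (direct KKT matrix construction and solve), and the
# empirical variogram as an explicit double loop over all pairs.

# Covariance of a bounded-family variogram model: sill on the diagonal
# (h = 0), sill - gamma(h) elsewhere.
oracle_cov <- function(model, h) {
  sill <- model$nugget + model$psill
  ifelse(h == 0, sill, sill - model_gamma(model, h))
}

# Constrained generalized-least-squares BLUP: minimize Var(Z0 - w'Z)
# subject to F'w = f0, via the covariance-form KKT system. Returns
# prediction and the error variance evaluated from the quadratic form.
oracle_blup <- function(sites, values, model, target, trend_order = NULL) {
  n <- nrow(sites)
  D <- as.matrix(dist(cbind(sites$x, sites$y)))
  C <- matrix(oracle_cov(model, as.vector(D)), n, n)
  d0 <- sqrt((sites$x - target[1])^2 + (sites$y - target[2])^2)
  c0 <- oracle_cov(model, d0)
  sill <- model$nugget + model$psill
  if (is.null(trend_order)) {
    F <- matrix(1, n, 1)
    f0 <- 1
  } else {
    mono <- function(x, y) {
      out <- cbind(1, x, y)
      if (trend_order == 2) out <- cbind(out, x^2, x * y, y^2)
      out
    }
    F <- mono(sites$x, sites$y)
    f0 <- drop(mono(target[1], target[2]))
  }
  p <- ncol(F)
  K <- rbind(cbind(C, F), cbind(t(F), matrix(0, p, p)))
  sol <- solve(K, c(c0, f0))
  w <- sol[1:n]
  pred <- sum(w * values)
  varr <- sill - 2 * sum(w * c0) + drop(t(w) %*% C %*% w)
  list(prediction = pred, variance = varr, weights = w)
}

# Joint-GLS cokriging oracle under an LMC: the covariance of variable pair
# (p, q) at lag h is sum_k B_k[p,q] * (1 - basis_k(h)), with the nugget
# basis equal to 0 at h = 0 and 1 elsewhere.
oracle_cok <- function(sites, z1, z2, lmc, target) {
  n <- nrow(sites)
  basis_at <- function(s, h) {
    switch(s$family,
      nugget = as.numeric(h > 0),
      spherical = ifelse(h >= s$range, 1, 1.5 * h / s$range - 0.5 * (h / s$range)^3),
      exponential = 1 - exp(-h / s$range),
      stop("oracle supports bounded families only")
    )
  }
  cov_pq <- function(h, p, q) {
    out <- 0
    for (k in seq_along(lmc$structures)) {
      out <- out + lmc$B[[k]][p, q] * (1 - basis_at(lmc$structures[[k]], h))
    }
    out
  }
  D <- as.matrix(dist(cbind(sites$x, sites$y)))
  C11 <- matrix(cov_pq(as.vector(D), 1, 1), n, n)
  C22 <- matrix(cov_pq(as.vector(D), 2, 2), n, n)
  C12 <- matrix(cov_pq(as.vector(D), 1, 2), n, n)
  d0 <- sqrt((sites$x - target[1])^2 + (sites$y - target[2])^2)
  c10 <- cov_pq(d0, 1, 1)
  c20 <- cov_pq(d0, 1, 2) # cov between covariate at sites and primary at target
  C <- rbind(cbind(C11, C12), cbind(t(C12), C22))
  F <- cbind(c(rep(1, n), rep(0, n)), c(rep(0, n), rep(1, n)))
  f0 <- c(1, 0)
  K <- rbind(cbind(C, F), cbind(t(F), matrix(0, 2, 2)))
  sol <- solve(K, c(c10, c20, f0))
  w <- sol[1:(2 * n)]
  pred <- sum(w * c(z1, z2))
  sill11 <- cov_pq(0, 1, 1)
  varr <- sill11 - 2 * sum(w * c(c10, c20)) + drop(t(w) %*% C %*% w)
  list(prediction = pred, variance = varr)
}

# All-pairs brute-force empirical variogram with the same binning rule.
oracle_variogram <- function(sites, values, lag_width, max_dist) {
  n <- nrow(sites)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      h <- sqrt((sites$x[i] - sites$x[j])^2 + (sites$y[i] - sites$y[j])^2)
      if (h > 0 && h <= max_dist) {
        rows[[length(rows) + 1]] <- c(h = h, sq = (values[i] - values[j])^2)
      }
    }
  }
  m <- do.call(rbind, rows)
  bin <- ceiling(m[, "h"] / lag_width)
  out <- data.frame(
    lag = tapply(m[, "h"], bin, mean),
    gamma = tapply(m[, "sq"], bin, sum) / (2 * tapply(m[, "sq"], bin, length)),
    np = as.integer(tapply(m[, "sq"], bin, length))
  )
  out[order(as.numeric(rownames(out))), ]
}

# Small reproducible site clouds for solver tests.
random_sites <- function(n, seed, width = 1000) {
  set.seed(seed)
  data.frame(x = runif(n, 0, width), y = runif(n, 0, width))
}

with_seed_rnorm <- function(seed, n, sd) {
  set.seed(seed)
  rnorm(n, 0, sd)
}
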