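test_that("residualization matches a per-column two-stage OLS oracle", {
  set.seed(1)
  n <- 20
  B <- matrix(stats::rnorm(n * 5), n)
  C <- matrix(stats::rnorm(n * 3), n)
  Xr <- residualize_block(B, C)
  D <- cbind(1, C)
  for (j in 1:5) {
    b <- solve(t(D) %*% D, t(D) %*% B[, j])
    r <- B[, j] - D %*% b
    expect_equal(Xr[, j], as.numeric(r / stats::sd(r)), tolerance = 1e-12)
    expect_equal(stats::sd(Xr[, j]), 1, tolerance = 1e-12)
  }
  # column that is pre-centered and empirically orthogonal to the covariates
  # comes back unchanged up to scale
  v <- stats::rnorm(n)
  v <- as.numeric(qr.resid(qr(D), v))
  out <- residualize_block(cbind(v), C)
  expect_equal(out[, 1], v / stats::sd(v), tolerance = 1e-12)
  # exact linear function of the covariates has no residual variance
  expect_error(residualize_block(cbind(bad = 2 * C[, 1] - C[, 2]), C), "bad")
})

test_that("fit_plsc handles self-correlated and orthogonal blocks exactly", {
  set.seed(2)
  x <- scale(stats::rnorm(30))
  f1 <- fit_plsc(x, x)
  expect_equal(f1$singular_values, 1, tolerance = 1e-12)
  expect_equal(abs(f1$x_saliences[1, 1]), 1, tolerance = 1e-12)
  expect_equal(abs(f1$y_saliences[1, 1]), 1, tolerance = 1e-12)
  # blocks with exactly zero cross-products
  X <- cbind(c(1, 1, -1, -1), c(1, -1, 1, -1))
  Y <- cbind(c(1, -1, -1, 1))
  expect_equal(fit_plsc(X, Y)$singular_values, 0, tolerance = 1e-12)
})

test_that("fit_plsc agrees with the eigen-decomposition oracle on random blocks", {
  set.seed(3)
  for (i in 1:25) {
    blocks <- make_null_blocks(30, 4, 3)
    fit <- fit_plsc(blocks$X, blocks$Y)
    o <- oracle_plsc(blocks$X, blocks$Y)
    expect_equal(fit$singular_values, o$sigma, tolerance = 1e-10)
    for (k in 1:3) {
      expect_equal(abs(fit$y_saliences[, k]), abs(o$U[, k]), tolerance = 1e-8)
      expect_equal(abs(fit$x_saliences[, k]), abs(o$V[, k]), tolerance = 1e-8)
    }
    # conservation: sum of squared singular values = squared Frobenius norm
    expect_equal(sum(fit$singular_values^2), sum(o$R^2), tolerance = 1e-10)
    # LV score covariances reproduce the singular values
    cv <- diag(crossprod(fit$x_scores, fit$y_scores) / (30 - 1))
    expect_equal(cv, fit$singular_values, tolerance = 1e-10)
    # sign convention: largest-|.| Y element positive
    for (k in 1:3) {
      j <- which.max(abs(fit$y_saliences[, k]))
      expect_gte(fit$y_saliences[j, k], 0)
    }
  }
})

test_that("covariance-explained fractions are exact and sum to one", {
  expect_equal(covariance_explained(c(4, 3)), c(0.64, 0.36))
  expect_equal(covariance_explained(c(2, 0, 0)), c(1, 0, 0))
  set.seed(4)
  for (i in 1:20) {
    s <- sort(stats::runif(sample(2:6, 1), 0, 5), decreasing = TRUE)
    expect_equal(sum(covariance_explained(s)), 1, tolerance = 1e-12)
  }
  expect_error(covariance_explained(c(0, 0)), "zero")
  expect_error(covariance_explained(c(-1, 2)), "non-negative")
})

test_that("permutation p hits the add-one floor under overwhelming structure", {
  set.seed(5)
  blocks <- make_planted_blocks(100, rep(1, 5), rep(1, 3), 0.05, 0.05)
  Xr <- residualize_block(blocks$X)
  Yr <- residualize_block(blocks$Y)
  perm <- plsc_permutation(Xr, Yr, n_perm = 300, seed = 6)
  expect_equal(perm$omnibus_p, 1 / 301, tolerance = 1e-12)
  expect_equal(perm$lv_p[1], 1 / 301, tolerance = 1e-12)
  # determinism under the seed
  perm2 <- plsc_permutation(Xr, Yr, n_perm = 300, seed = 6)
  expect_identical(perm, perm2)
  expect_error(plsc_permutation(Xr, Yr, n_perm = 50), "at least 100")
})

test_that("bootstrap CIs are seeded, sign-equivariant and flag planted structure", {
  set.seed(7)
  blocks <- make_planted_blocks(120, c(1, 1, 1, 0, 0), c(1, 1, 0),
                                0.3, 0.3)
  Xr <- residualize_block(blocks$X)
  Yr <- residualize_block(blocks$Y)
  fit <- fit_plsc(Xr, Yr)
  b1 <- plsc_bootstrap(Xr, Yr, n_boot = 400, seed = 8, fit = fit)
  b2 <- plsc_bootstrap(Xr, Yr, n_boot = 400, seed = 8, fit = fit)
  expect_identical(b1, b2)
  # planted-nonzero X elements reliable on LV1, planted-zero ones not
  expect_true(all(b1$x_reliable[1:3, 1]))
  expect_true(all(b1$y_reliable[1:2, 1]))
  # negating an X column mirrors that column's salience and CI
  Xr2 <- Xr; Xr2[, 2] <- -Xr2[, 2]
  fit2 <- fit_plsc(Xr2, Yr)
  expect_equal(fit2$x_saliences[2, ], -fit$x_saliences[2, ], tolerance = 1e-10)
  b3 <- plsc_bootstrap(Xr2, Yr, n_boot = 400, seed = 8, fit = fit2)
  expect_equal(b3$x_ci_lower[2, 1], -b1$x_ci_upper[2, 1], tolerance = 1e-10)
  expect_equal(b3$x_ci_upper[2, 1], -b1$x_ci_lower[2, 1], tolerance = 1e-10)
  expect_error(plsc_bootstrap(Xr, Yr, n_boot = 100), "at least 200")
})

test_that("full PLS-C detects planted structure and respects the 5% report rule", {
  set.seed(9)
  blocks <- make_planted_blocks(150, c(1, 1, 1, 1, 0, 0, 0, 0),
                                c(1, 1, 1, 0), 0.5, 0.5)
  C <- data.frame(age = stats::rnorm(150, 24, 3))
  res <- plsc(blocks$X, blocks$Y, C, n_perm = 500, n_boot = 500, seed = 10)
  expect_lt(res$omnibus_p, 0.05)
  expect_true(res$reportable[1])
  expect_true(res$cov_explained[1] > 0.5)
  expect_equal(sum(res$cov_explained), 1, tolerance = 1e-10)
  o <- order(res$singular_values, decreasing = TRUE)
  expect_identical(o, seq_along(o))
})

test_that("group-wise PLS-C localizes structure to the group that carries it", {
  set.seed(11)
  n1 <- 80; n2 <- 80
  planted <- make_planted_blocks(n1, c(1, 1, 1, 0, 0, 0), c(1, 1, 0), 0.4, 0.4)
  nullb <- make_null_blocks(n2, 6, 3)
  X <- rbind(planted$X, nullb$X)
  Y <- rbind(planted$Y, nullb$Y)
  g <- rep(c("carrier", "none"), c(n1, n2))
  res <- groupwise_plsc(X, Y, g, n_perm = 300, n_boot = 300, seed = 12)
  expect_lt(res$within$carrier$omnibus_p, 0.05)
  expect_gt(res$within$none$omnibus_p, 0.05)
  expect_lt(res$contrast_p, 0.05)
  # identical data in both groups: contrast consistent with the null
  Xd <- rbind(planted$X, planted$X)
  Yd <- rbind(planted$Y, planted$Y)
  gd <- rep(c("a", "b"), each = n1)
  resd <- groupwise_plsc(Xd, Yd, gd, n_perm = 300, n_boot = 300, seed = 13)
  expect_gt(resd$contrast_p, 0.05)
  # seeded reproducibility
  resd2 <- groupwise_plsc(Xd, Yd, gd, n_perm = 300, n_boot = 300, seed = 13)
  expect_identical(resd$contrast_p, resd2$contrast_p)
})
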