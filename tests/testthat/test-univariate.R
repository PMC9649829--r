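test_that("group F equals the squared pooled t with no covariates", {
  set.seed(1)
  y <- stats::rnorm(40)
  g <- rep(c("a", "b"), each = 20)
  res <- glm_group_test(y, g)
  tt <- stats::t.test(y ~ g, var.equal = TRUE)
  expect_equal(res$f_stat, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("group F matches an explicit normal-equations oracle on a 12-subject toy", {
  set.seed(2)
  g <- rep(0:1, each = 6)
  C <- cbind(age = stats::rnorm(12, 24, 3), sex = rep(0:1, 6))
  y <- 0.5 * g + 0.02 * C[, 1] + stats::rnorm(12)
  res <- glm_group_test(y, factor(g), as.data.frame(C))
  # oracle: solve both models by normal equations
  Xf <- cbind(1, g, C); Xr <- cbind(1, C)
  bf <- solve(t(Xf) %*% Xf, t(Xf) %*% y)
  br <- solve(t(Xr) %*% Xr, t(Xr) %*% y)
  rss_f <- sum((y - Xf %*% bf)^2)
  rss_r <- sum((y - Xr %*% br)^2)
  f_oracle <- (rss_r - rss_f) / (rss_f / (12 - 4))
  expect_equal(res$f_stat, f_oracle, tolerance = 1e-10)
  expect_equal(res$df_den, 8)
  # adjusted mean difference equals the group coefficient
  expect_equal(unname(diff(res$adjusted_means)), unname(bf[2]),
               tolerance = 1e-10)
})

test_that("null group effect gives near-uniform p-values", {
  set.seed(3)
  p <- replicate(400, {
    y <- stats::rnorm(30)
    glm_group_test(y, rep(c("a", "b"), 15),
                   data.frame(c1 = stats::rnorm(30)))$p_value
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("rank-deficient designs are rejected naming the collinear column", {
  y <- stats::rnorm(20)
  g <- rep(0:1, 10)
  expect_error(glm_group_test(y, g, data.frame(dup = g)), "dup")
})

test_that("partial correlation reduces to Pearson and handles exact dependence", {
  set.seed(4)
  x <- stats::rnorm(30); y <- stats::rnorm(30)
  expect_equal(partial_correlation(x, y, B = 0)$r, stats::cor(x, y),
               tolerance = 1e-12)
  C <- data.frame(a = stats::rnorm(30))
  expect_equal(partial_correlation(x, x, C, B = 0)$r, 1, tolerance = 1e-12)
  expect_error(partial_correlation(x, 2 * C$a + 1, C, B = 0),
               "residual variance")
})

test_that("partial correlation matches the two-stage OLS oracle", {
  # 8-subject toy, stepped through the oracle
  x8 <- c(1.2, 0.8, -0.3, 2.1, -1.4, 0.5, -0.9, 1.0)
  y8 <- c(0.9, 1.1, -0.2, 1.8, -1.0, 0.1, -1.2, 0.6)
  C8 <- data.frame(age = c(21, 25, 23, 28, 22, 24, 26, 23),
                   sex = c(0, 1, 0, 1, 1, 0, 0, 1))
  res <- partial_correlation(x8, y8, C8, B = 0)
  expect_equal(res$r, oracle_partial_cor(x8, y8, C8), tolerance = 1e-12)
  expect_equal(res$df, 8 - 2 - 2)
  set.seed(5)
  for (i in 1:30) {
    n <- sample(10:60, 1)
    k <- sample(1:4, 1)
    x <- stats::rnorm(n); y <- stats::rnorm(n)
    C <- matrix(stats::rnorm(n * k), n)
    expect_equal(partial_correlation(x, y, C, B = 0)$r,
                 oracle_partial_cor(x, y, C), tolerance = 1e-12)
  }
})

test_that("partial-correlation bootstrap is seeded and brackets the estimate", {
  set.seed(6)
  x <- stats::rnorm(50); y <- 0.6 * x + stats::rnorm(50)
  C <- data.frame(a = stats::rnorm(50))
  r1 <- partial_correlation(x, y, C, B = 300, seed = 9)
  r2 <- partial_correlation(x, y, C, B = 300, seed = 9)
  expect_identical(r1$ci, r2$ci)
  expect_lt(r1$ci[1], r1$r)
  expect_gt(r1$ci[2], r1$r)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.21, 6)), rep(0.21, 6))
  set.seed(7)
  for (i in 1:30) {
    p <- stats::runif(sample(2:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    # monotone in sorted-p order, never below raw p, capped at 1
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    expect_true(all(q >= p - 1e-12) && all(q <= 1))
  }
  expect_error(bh_fdr(c(0.2, 1.3)), "0, 1")
})

test_that("mediation satisfies the OLS decomposition and recovers planted paths", {
  set.seed(8)
  n <- 200
  x <- stats::rnorm(n)
  m <- 0.7 * x + stats::rnorm(n)
  y <- 0.3 * x + 0.5 * m + stats::rnorm(n)
  res <- mediate(x, m, y, B = 200, seed = 3)
  expect_equal(res$c, res$c_prime + res$indirect, tolerance = 1e-10)
  # b = 0 by construction: indirect near zero, CI covers 0
  y0 <- 0.4 * x + stats::rnorm(n)
  res0 <- mediate(x, m, y0, B = 500, seed = 4)
  expect_lt(res0$ci[1], 0)
  expect_gt(res0$ci[2], 0)
  # with covariates the identity still holds exactly
  C <- data.frame(a = stats::rnorm(n))
  resc <- mediate(x, m, y, C, B = 0)
  expect_equal(resc$c, resc$c_prime + resc$indirect, tolerance = 1e-10)
})
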