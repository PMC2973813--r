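# KDE and mode detection, correlations, partial correlations, regression.

test_that("gaussian_kde integrates to ~1 and finds planted modes", {
  set.seed(21)
  x <- c(rnorm(100, 0.18, 0.05), rnorm(100, 3.0, 0.5))
  kd <- gaussian_kde(x)
  integral <- sum(diff(kd$grid) * (head(kd$density, -1) + tail(kd$density, -1)) / 2)
  expect_lt(abs(integral - 1), 0.01)
  expect_length(kd$modes, 2L)
  expect_lt(abs(kd$modes[[1L]] - 0.18), 0.1)
  expect_lt(abs(kd$modes[[2L]] - 3.0), 0.5)
})

test_that("gaussian_kde single cluster and duplication invariance", {
  set.seed(22)
  x <- rnorm(80, 1.5, 0.1)
  kd <- gaussian_kde(x)
  expect_length(kd$modes, 1L)
  # grid discretization and sample skew can shift the peak slightly past h
  expect_lt(abs(kd$modes[[1L]] - mean(x)), 2 * kd$bandwidth)
  # duplicating the sample leaves the density shape unchanged (same bandwidth)
  kd2 <- gaussian_kde(c(x, x), bandwidth = kd$bandwidth)
  expect_equal(kd2$density, kd$density, tolerance = 1e-8)
  expect_error(gaussian_kde(rep(1, 10)), class = "degenerate_density_error")
  expect_error(gaussian_kde(c(1, 2)), class = "kde_input_error")
})

test_that("pearson_test matches the covariance formula and exact limits", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  ct <- pearson_test(x, y)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ct$r, r_direct, tolerance = 1e-12)
  lin <- pearson_test(x, 2 * x + 1)
  expect_equal(lin$r, 1)
  expect_lt(lin$p, 1e-10)
  expect_error(pearson_test(x, rep(1, 5)), class = "zero_variance_error")
})

test_that("pearson_test null calibration: p is ~uniform under independence", {
  set.seed(31)
  ps <- replicate(300, pearson_test(rnorm(30), rnorm(30))$p)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.035)
})

test_that("partial_correlation equals the residual-regression oracle", {
  set.seed(41)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    z <- rnorm(n)
    x <- 0.5 * z + rnorm(n)
    y <- -0.3 * z + 0.4 * x + rnorm(n)
    pc <- partial_correlation(x, y, z)
    oracle <- cor(resid(lm(x ~ z)), resid(lm(y ~ z)))
    expect_equal(pc$r, oracle, tolerance = 1e-10)
  }
})

test_that("partial_correlation limits and degeneracy", {
  set.seed(42)
  x <- rnorm(50); y <- 0.6 * x + rnorm(50); z <- rnorm(50)
  pc <- partial_correlation(x, y, z)
  expect_lt(abs(pc$r - cor(x, y)), 0.15)  # z independent: near plain r
  expect_error(partial_correlation(x, y, y),
               class = "degenerate_partial_error")
})

test_that("strength_ks_regression recovers planted slopes and filters", {
  # noise-free planted line is recovered exactly
  ks <- seq(0.1, 1.9, length.out = 20)
  exact <- strength_ks_regression(
    data.frame(strength = 0.41 * ks - 0.8, ks = ks))
  expect_equal(exact$slope, 0.41, tolerance = 1e-10)
  expect_equal(exact$intercept, -0.8, tolerance = 1e-10)
  # planted noisy recovery at the default decay parameters
  d <- simulate_buffering_decay(n = 50, seed = 7)
  fit <- strength_ks_regression(d)
  expect_gte(fit$slope, 0.35); expect_lte(fit$slope, 0.47)
  expect_equal(fit$n, 50L)
  # everything saturated -> the filter errors by name
  expect_error(
    strength_ks_regression(data.frame(strength = rnorm(10),
                                      ks = runif(10, 2.5, 4))),
    regexp = "saturation", class = "saturation_filter_error")
})

test_that("neutral_mode_report separates neutral from selection worlds", {
  d <- simulate_buffering_decay(n = 50, seed = 13)
  rep1 <- neutral_mode_report(d)
  expect_lt(rep1$partial_ks_strength$p, 0.05)
  expect_gt(rep1$partial_ka_strength$p, 0.05)
  expect_equal(rep1$partial_ks_strength$controlled_for, "ka")
  # selection world: strength independent of both
  set.seed(14)
  sel <- data.frame(ks = runif(50, 0.1, 2), ka = runif(50, 0.01, 0.5),
                    strength = rnorm(50, -0.4, 0.1))
  rep2 <- neutral_mode_report(sel)
  expect_lt(abs(rep2$partial_ks_strength$r), 0.35)
  expect_lt(abs(rep2$partial_ka_strength$r), 0.35)
  expect_error(neutral_mode_report(data.frame()), class = "empty_input_error")
})
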