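test_that("ICC(3,1) matches the ANOVA mean-squares oracle on a fixture", {
  m <- matrix(c(7, 5, 8, 6, 9, 4, 8, 5, 9, 7, 10, 5), ncol = 2)
  # independent oracle: mean squares from stats::aov on the long layout
  long <- data.frame(v = c(m), row = factor(rep(1:6, 2)),
                     col = factor(rep(1:2, each = 6)))
  av <- summary(stats::aov(v ~ row + col, data = long))[[1]]
  msr <- av["row", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  res <- icc3_1(m)
  expect_equal(res$icc, (msr - mse) / (msr + mse), tolerance = 1e-10)
  expect_equal(res$icc, 0.978540772532188, tolerance = 1e-10)
  expect_equal(res$f_value, msr / mse, tolerance = 1e-10)
  expect_equal(c(res$df1, res$df2), c(5, 5))
  expect_lte(res$ci_low, res$icc)
  expect_gte(res$ci_high, res$icc)
})

test_that("consistency ICC ignores fixed session offsets", {
  a <- c(1, 2, 3, 4, 5)
  expect_equal(icc3_1(cbind(a, a))$icc, 1)
  expect_equal(icc3_1(cbind(a, a + 0.2))$icc, 1)
  # and equals Pearson's r when column variances are equal
  set.seed(3)
  x <- rnorm(8)
  expect_equal(icc3_1(cbind(x, rev(x)))$icc, cor(x, rev(x)),
               tolerance = 1e-10)
  expect_error(icc3_1(cbind(1:2, 1:2)), "at least 3")
})

test_that("Bland-Altman bias and limits follow the 1.96 rule", {
  ba <- bland_altman(c(1, 2, 3, 4), c(1, 2, 3, 4) - c(0.1, -0.1, 0.3, -0.3))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, sd(c(0.1, -0.1, 0.3, -0.3)), tolerance = 1e-12)
  expect_equal(ba$loa_high, 1.96 * ba$sd_diff, tolerance = 1e-12)
  expect_equal(ba$loa_low, -ba$loa_high, tolerance = 1e-12)
  # identical and constant-shifted inputs
  a <- c(2, 4, 6)
  expect_equal(bland_altman(a, a)$loa_high, 0)
  shifted <- bland_altman(a, a + 1)
  expect_equal(shifted$bias, -1)
  expect_equal(shifted$loa_high - shifted$loa_low, 0)
  # antisymmetry of the bias
  expect_equal(bland_altman(a, a + 1)$bias, -bland_altman(a + 1, a)$bias)
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("the auto correlation method keys on Shapiro-Wilk normality", {
  a <- c(5.1, 4.9, 6.2, 5.5, 4.4, 5.8, 6.0, 5.2)
  lin <- correlate(a, 2 * a + 3, method = "pearson")
  expect_equal(lin$statistic, 1)
  # a heavy-tailed margin pushes auto to Spearman; a cubic monotone map
  # still earns rho = 1
  b <- c(1:9, 30)
  res <- correlate(b, b^3, method = "auto")
  expect_equal(res$method, "spearman")
  expect_equal(res$statistic, 1)
  # near-normal margins keep Pearson
  res2 <- correlate(a, 2 * a + 3 + seq(-0.02, 0.015, length.out = 8),
                    method = "auto")
  expect_equal(res2$method, "pearson")
  expect_error(correlate(rep(1, 5), 1:5), "constant")
})

test_that("paired comparisons report Cohen's d as t over root n", {
  set.seed(12)
  a <- rnorm(30, 0.6, 0.1)
  b <- rnorm(30, 0.5, 0.1)
  res <- paired_comparison(a, b)
  expect_equal(res$effect_size, res$statistic / sqrt(30), tolerance = 1e-12)
  expect_equal(res$df, 29)
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(res$statistic, unname(tt$statistic))
  expect_equal(res$p_value, tt$p.value)
  expect_error(paired_comparison(a, a), "zero variance")
})

test_that("the exact power model reproduces the planning sample size", {
  expect_equal(required_n_correlation(0.35, alpha = 0.05, power = 0.8,
                                      tails = "one"), 49L)
  # Fisher-z approximation lands one higher
  expect_equal(required_n_correlation(0.35, alpha = 0.05, power = 0.8,
                                      tails = "one", method = "fisher"), 50L)
})

test_that("the sample-correlation density integrates to one", {
  for (n in c(10, 49)) {
    expect_equal(stats::integrate(dsamplecor, -1, 1, n = n, rho = 0.35,
                                  rel.tol = 1e-10)$value, 1, tolerance = 1e-7)
  }
})

test_that("required n is monotone in rho, alpha and power", {
  n_mid <- required_n_correlation(0.35)
  expect_lte(required_n_correlation(0.6), n_mid)
  expect_lte(required_n_correlation(0.35, alpha = 0.10), n_mid)
  expect_gte(required_n_correlation(0.35, power = 0.9), n_mid)
  expect_lte(required_n_correlation(0.95), 7)
})
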