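test_that("partial eta squared reproduces the reported effect sizes", {
  expect_equal(round(partialEtaSq(8.05, 1, 52), 2), 0.13)
  expect_equal(round(partialEtaSq(5.15, 1, 52), 2), 0.09)
  expect_equal(round(partialEtaSq(9.59, 1, 52), 2), 0.16)
  expect_equal(round(partialEtaSq(7.68, 1, 49), 2), 0.14)
  expect_equal(round(partialEtaSq(5.87, 1, 49), 2), 0.11)
  expect_equal(round(partialEtaSq(10.13, 1, 49), 2), 0.17)
  ci <- partialEtaSqCi(8.05, 1, 52)
  expect_equal(round(unname(ci), 2), c(0.02, 1.00))
  expect_equal(unname(partialEtaSqCi(0.1, 1, 52)["lower"]), 0)
})

test_that("one-way ANOVA matches a hand decomposition on 6 numbers", {
  r <- oneWayAnova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(r$F, 13.5)
  expect_equal(c(r$df1, r$df2), c(1, 4))
  expect_equal(r$partialEtaSq, 13.5 / (13.5 + 4))
  # identical group means: F = 0, eta = 0
  r0 <- oneWayAnova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(r0$F, 0)
  expect_equal(r0$partialEtaSq, 0)
  expect_error(oneWayAnova(1:4, c("a", "a", "a", "b")), "n >= 2")
})

test_that("two-group ANOVA equals the squared pooled t", {
  set.seed(20)
  x <- rnorm(14); y <- rnorm(11, 0.8)
  a <- oneWayAnova(c(x, y), rep(c("x", "y"), c(14, 11)))
  t <- twoSampleT(x, y)
  expect_equal(a$F, t$t^2, tolerance = 1e-10)
  expect_equal(a$meanDiff, t$meanDiff)
  expect_equal(unname(a$meanDiffCi), t$ci, tolerance = 1e-12)
})

test_that("moment-matched samples reproduce the printed group contrast", {
  u <- momentNormalSample(30, -0.080, 0.033)
  v <- momentNormalSample(24, -0.052, 0.040)
  expect_equal(mean(u), -0.080, tolerance = 1e-12)
  expect_equal(sd(u), 0.033, tolerance = 1e-12)
  t <- twoSampleT(u, v)
  expect_equal(t$meanDiff, -0.028, tolerance = 1e-12)
  expect_equal(round(t$ci, 3), c(-0.048, -0.008))
  expect_equal(round(t$d, 2), -0.77)
})

test_that("t and d agree with hand arithmetic on 4 numbers", {
  r <- twoSampleT(c(0, 1), c(1, 2))
  expect_equal(r$meanDiff, -1)
  expect_equal(round(r$d, 3), -1.414)
  # identical samples: zero everywhere
  r0 <- twoSampleT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$t, 0)
  expect_equal(r0$d, 0)
  expect_error(twoSampleT(c(1, 1), c(1, 1)), "zero pooled")
})

test_that("chi-square reproduces the phase-by-group table", {
  phase <- matrix(c(8, 4, 2, 6, 4, 1, 6, 6, 3), nrow = 3, byrow = TRUE)
  r <- contingencyTest(phase, "chi_square")
  expect_equal(round(r$statistic, 2), 1.28)
  expect_equal(r$df, 4)
  expect_equal(r$statistic, oracleChisq(phase), tolerance = 1e-12)
  # independence: chi2 = 0, Fisher p = 1
  even <- matrix(c(5, 5, 5, 5), 2)
  expect_equal(contingencyTest(even, "chi_square")$statistic, 0)
  expect_equal(contingencyTest(even, "fisher")$p, 1)
  expect_error(contingencyTest(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("Fisher exact p equals exhaustive hypergeometric enumeration", {
  tabs <- list(matrix(c(13, 14, 10, 3), 2),
               matrix(c(2, 8, 7, 1), 2),
               matrix(c(0, 5, 6, 2), 2),
               matrix(c(9, 9, 9, 9), 2))
  for (tab in tabs)
    expect_equal(contingencyTest(tab, "fisher")$p, oracleFisher2x2(tab),
                 tolerance = 1e-12)
})

test_that("Wilcoxon rank-sum switches between exact and approximate", {
  set.seed(21)
  small <- wilcoxonRankSum(rnorm(8), rnorm(9, 1))
  expect_equal(small$method, "exact")
  big <- wilcoxonRankSum(rnorm(30), rnorm(30, 0.5))
  expect_equal(big$method, "normal approximation")
  tied <- wilcoxonRankSum(c(1, 2, 2, 3), c(2, 3, 3, 4))
  expect_equal(tied$method, "normal approximation")
  expect_true(small$p >= 0 && small$p <= 1)
})

test_that("normality screen accepts normal and rejects exponential data", {
  set.seed(22)
  pNorm <- replicate(200, ksNormality(rnorm(500))$p)
  pExp <- replicate(200, ksNormality(rexp(500))$p)
  expect_gte(mean(pNorm > 0.05), 0.90)
  expect_gte(mean(pExp < 0.05), 0.90)
  expect_error(ksNormality(rep(1, 10)), "degenerate")
  expect_error(ksNormality(rnorm(4)), "at least 5")
})
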