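test_that("Friedman statistic matches the rank oracle and known cases", {
  # n = 4 subjects, strictly ordered columns: chi-square = 8
  m <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12), nrow = 4)
  res <- friedman_bonferroni(m)
  expect_equal(res$omnibus$statistic, 8)
  expect_equal(res$omnibus$statistic, oracle_friedman_stat(m))
  # agrees with the reference implementation
  expect_equal(res$omnibus$statistic,
               unname(stats::friedman.test(m)$statistic))
  expect_equal(res$omnibus$p, stats::friedman.test(m)$p.value)

  # identical columns: statistic 0, omnibus and all pairwise p = 1
  m0 <- matrix(rep(c(3, 1, 4, 1, 5), 3), ncol = 3)
  res0 <- friedman_bonferroni(m0)
  expect_equal(res0$omnibus$statistic, 0)
  expect_equal(res0$omnibus$p, 1)
  expect_true(all(res0$pairwise$p_adjusted == 1))

  # random (tied) data still matches friedman.test
  set.seed(12)
  for (i in 1:20) {
    mr <- matrix(sample(1:4, 18, replace = TRUE), ncol = 3)
    if (all(apply(mr, 1, function(r) length(unique(r))) == 1)) next
    expect_equal(friedman_bonferroni(mr)$omnibus$statistic,
                 unname(stats::friedman.test(mr)$statistic),
                 label = paste("replicate", i))
  }
})

test_that("Friedman statistic is invariant under strictly monotone transforms", {
  set.seed(3)
  for (i in 1:25) {
    m <- matrix(stats::rnorm(15), ncol = 3)
    s1 <- friedman_bonferroni(m)$omnibus$statistic
    s2 <- friedman_bonferroni(exp(2 * m) + 1)$omnibus$statistic
    expect_equal(s1, s2)
  }
})

test_that("exhaustive-permutation oracle matches for n <= 5 subjects", {
  set.seed(21)
  for (n in c(3, 4)) {
    m <- matrix(stats::rnorm(n * 3), ncol = 3)
    res <- friedman_bonferroni(m, p_method = "permutation")
    expect_equal(res$omnibus$p, oracle_friedman_perm_p(m), tolerance = 1e-12,
                 label = paste("n =", n))
  }
  m5 <- matrix(stats::rnorm(15), ncol = 3)
  res5 <- friedman_bonferroni(m5, p_method = "permutation")
  expect_equal(res5$omnibus$p, oracle_friedman_perm_p(m5), tolerance = 1e-12)
})

test_that("Pratt signed-rank z matches the exact sign-flip distribution", {
  set.seed(14)
  for (i in 1:15) {
    x <- sample(0:6, 8, replace = TRUE)
    y <- sample(0:6, 8, replace = TRUE)
    if (all(x == y)) next
    w <- wilcoxon_pratt(x, y, exact = TRUE)
    expect_equal(w$p, oracle_wilcoxon_exact_p(x, y), tolerance = 1e-12,
                 label = paste("replicate", i))
  }
  # all-tied pairs: z = 0, p = 1
  w0 <- wilcoxon_pratt(1:5, 1:5)
  expect_equal(w0$z, 0)
  expect_equal(w0$p, 1)
})

test_that("Pratt z agrees with the standard normal approximation without zeros", {
  # no zero differences, no ties in |d|: z^2 relates to wilcox.test's
  # uncorrected normal approximation p
  x <- c(10.2, 8.1, 12.5, 9.9, 14.1, 7.7, 11.3, 13.8)
  y <- c(9.1, 8.9, 10.2, 11.5, 12.0, 9.3, 10.1, 12.2)
  w <- wilcoxon_pratt(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                            correct = FALSE)
  expect_equal(w$p, ref$p.value, tolerance = 1e-10)
})

test_that("Rosenthal's r follows |z|/sqrt(N) with both N conventions", {
  expect_equal(rosenthal_r(2, 10)$r, 2 / sqrt(20))
  expect_equal(rosenthal_r(2, 10)$label, "Small")
  expect_equal(rosenthal_r(2, 10, n_convention = "n")$r, 2 / sqrt(10))
  expect_equal(rosenthal_r(0, 5)$r, 0)
  expect_equal(rosenthal_r(0, 5)$label, "Trivial")
  expect_equal(rosenthal_r(-2, 10)$r, rosenthal_r(2, 10)$r)
  expect_error(rosenthal_r(Inf, 10), "finite")
})

test_that("paired Cohen's d and the magnitude bands behave as documented", {
  expect_warning(d0 <- cohens_d_paired(1:5, 1:5), "zero variance")
  expect_true(is.na(d0$d))
  # differences with mean equal to their sd give d = 1, Large
  x <- c(3, 4, 5); y <- c(2, 2, 2)  # d = (1,2,3): mean 2, sd 1 -> d = 2
  expect_equal(cohens_d_paired(x, y)$d, 2)
  expect_equal(cohens_d_paired(x, y)$label, "Very large")
  x2 <- c(1, 2, 3) + c(0.9, 2.0, 3.1)  # diffs (0.9,2,3.1): mean 2, sd 1.1
  expect_equal(cohens_d_paired(x2, c(1, 2, 3))$d, 2 / 1.1)
  expect_equal(effect_size_label(0.19, "d"), "Trivial")
  expect_equal(effect_size_label(1.3, "d"), "Very large")
  expect_equal(effect_size_label(0.5, "d"), "Moderate")
  expect_equal(effect_size_label(0.79, "d"), "Moderate")
})

test_that("RM-ANOVA reduces to the paired t in two conditions, F = t^2", {
  set.seed(9)
  m <- matrix(stats::rnorm(20, sd = 2), ncol = 2)
  f <- rm_anova_bonferroni(m)
  t2 <- stats::t.test(m[, 1], m[, 2], paired = TRUE)$statistic^2
  expect_equal(f$omnibus$statistic, unname(t2), tolerance = 1e-8)
})

test_that("RM-ANOVA is location-invariant and degenerate-safe", {
  set.seed(10)
  m <- matrix(stats::rnorm(15), ncol = 3)
  a <- rm_anova_bonferroni(m)
  b <- rm_anova_bonferroni(m + 100)
  expect_equal(a$omnibus$statistic, b$omnibus$statistic)
  expect_equal(a$omnibus$p, b$omnibus$p)
  expect_equal(a$pairwise$effect_size, b$pairwise$effect_size)

  mm <- matrix(rep(c(1, 2, 3, 4, 5), 3), ncol = 3)
  dd <- rm_anova_bonferroni(mm)
  expect_true(dd$omnibus$degenerate)
  expect_equal(dd$omnibus$statistic, 0)
  expect_equal(dd$omnibus$p, 1)
})

test_that("normality routing picks the family the data support", {
  set.seed(77)
  # heavily skewed data at n = 10 reject normality
  skew <- matrix(stats::rlnorm(30, sdlog = 2.5)^2, ncol = 3)
  expect_equal(route_test(skew), "nonparametric")
  # degenerate ties route nonparametric
  ties <- matrix(rep(c(1, 1, 1, 1, 1), 3), ncol = 3)
  expect_equal(route_test(ties), "nonparametric")
  # large normal draws route parametric most of the time
  n_param <- sum(vapply(1:100, function(i) {
    route_test(matrix(stats::rnorm(120), ncol = 3)) == "parametric"
  }, logical(1)))
  expect_gt(n_param, 75)  # (1 - alpha)^3 ~ 0.857 expected
  expect_error(route_test(matrix(c(1, NA, 3, 4, 5, 6), ncol = 3)), "missing")
})

test_that("Bonferroni adjustment multiplies by 3 and caps at 1", {
  set.seed(15)
  m <- matrix(stats::rnorm(15), ncol = 3)
  res <- friedman_bonferroni(m)
  expect_true(all(res$pairwise$p_adjusted >= res$pairwise$p_raw))
  expect_true(all(res$pairwise$p_adjusted <= 1))
  expect_equal(res$pairwise$p_adjusted,
               pmin(1, res$pairwise$p_raw * 3))
})

test_that("compare_tests dispatches by routing and labels the variable", {
  set.seed(44)
  m <- matrix(stats::rnorm(30, mean = rep(c(0, 1, 2), each = 10)), ncol = 3)
  colnames(m) <- c("T0", "T1", "T2")
  res <- compare_tests(m, variable = "mean_volume")
  expect_s3_class(res, "cpr_comparison")
  expect_equal(res$variable, "mean_volume")
  expect_identical(res$pairwise$comparison,
                   c("T0 vs T1", "T0 vs T2", "T1 vs T2"))
})
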