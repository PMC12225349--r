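test_that("build_tables forms the three category-pair tables", {
  tabs <- build_tables(table3_counts())
  expect_named(tabs, c("green_vs_amber", "green_vs_red", "amber_vs_red"))
  expect_equal(unname(tabs$green_vs_red),
               cbind(c(0, 6, 24), c(125, 49, 28)))
  expect_equal(unname(colSums(tabs$green_vs_amber)), c(30, 149))
  expect_equal(unname(colSums(tabs$green_vs_red)), c(30, 202))
  zero <- matrix(0L, 3, 3, dimnames = dimnames(table3_counts()))
  tabs0 <- build_tables(zero)
  expect_true(all(vapply(tabs0, sum, numeric(1)) == 0))
  bad <- table3_counts(); bad[1, 1] <- -1
  expect_error(build_tables(bad), "non-negative")
})

test_that("chi-square is the uncorrected Pearson statistic", {
  # proportional rows are exactly independent
  prop <- rbind(c(10, 20), c(20, 40))
  cs <- chi_square(prop)
  expect_equal(cs$statistic, 0)
  expect_equal(cs$p, 1)

  # green-vs-amber from the printed counts: ~10.47 on 2 df, p rounds to 0.005
  tab <- build_tables(table3_counts())$green_vs_amber
  cs <- chi_square(tab)
  expect_equal(cs$statistic, 10.47, tolerance = 5e-3)
  expect_equal(cs$df, 2)
  expect_equal(round(cs$p, 3), 0.005)

  # invariant to transposition
  t22 <- rbind(c(7, 3), c(2, 9))
  expect_equal(chi_square(t22)$statistic, chi_square(t(t22))$statistic)

  expect_error(chi_square(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("chi-square matches the sum((O-E)^2/E) oracle on random tables", {
  set.seed(66)
  for (i in 1:60) {
    r <- sample(2:4, 1); c <- sample(2:4, 1)
    tab <- matrix(stats::rpois(r * c, 8) + 1, r, c)
    expect_equal(chi_square(tab)$statistic, oracle_chisq(tab),
                 tolerance = 1e-10, label = paste("table", i))
  }
})

test_that("chi-square p approximates the permutation null", {
  # cell sizes comparable to the study's pooled tables, where the
  # asymptotic null is adequate
  set.seed(91)
  tab <- rbind(c(60, 48), c(42, 56))
  cs <- chi_square(tab)
  sim <- stats::chisq.test(tab, correct = FALSE, simulate.p.value = TRUE,
                           B = 40000)
  expect_lt(abs(cs$p - sim$p.value), 0.01)
})

test_that("Cramer's V has the closed form, bounds and reference values", {
  # diagonal 2x2: V = 1; independence: V = 0
  expect_equal(cramers_v(diag(c(5, 5)))$v, 1)
  expect_equal(cramers_v(rbind(c(10, 20), c(20, 40)))$v, 0)

  tabs <- build_tables(table3_counts())
  expect_equal(round(cramers_v(tabs$green_vs_amber)$v, 2), 0.24)
  expect_equal(round(cramers_v(tabs$green_vs_red)$v, 2), 0.55)
  expect_equal(round(cramers_v(tabs$amber_vs_red)$v, 2), 0.50)
  # amber-vs-red T0 vs T2 sub-table: 0.58; labels follow the V scale
  sub <- tabs$amber_vs_red[c("T0", "T2"), ]
  cv <- cramers_v(sub)
  expect_equal(round(cv$v, 2), 0.58)
  expect_equal(cv$label, "Large")
  set.seed(52)
  for (i in 1:30) {
    tab <- matrix(stats::rpois(6, 10) + 1, 3, 2)
    v <- cramers_v(tab)$v
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("pairwise decomposition reproduces printed V values and verdicts", {
  tabs <- build_tables(table3_counts())
  pw <- pairwise_decomposition(tabs$green_vs_red)
  expect_equal(round(pw$cramers_v, 2), c(0.28, 0.61, 0.39))
  expect_true(all(pw$significant))

  pw2 <- pairwise_decomposition(tabs$amber_vs_red)
  expect_equal(round(pw2$cramers_v, 2), c(0.40, 0.58, 0.21))
  expect_equal(round(pw2$p[3], 3), 0.002)

  pw3 <- pairwise_decomposition(tabs$green_vs_amber)
  expect_equal(round(pw3$cramers_v[2], 2), 0.24)
  expect_equal(round(pw3$p[2], 3), 0.009)
  # T0 vs T1 (p = 0.12) and T1 vs T2 (p = 0.027) fail the 0.0167 threshold
  expect_identical(pw3$significant, c(FALSE, TRUE, FALSE))

  # identical rows: p = 1, not significant
  same <- rbind(c(5, 10), c(5, 10), c(5, 10))
  rownames(same) <- c("T0", "T1", "T2")
  pws <- pairwise_decomposition(same)
  expect_true(all(pws$p == 1))
  expect_false(any(pws$significant))
})

test_that("odds ratios use the cross-product with Woolf intervals", {
  expect_equal(odds_ratio(rbind(c(1, 1), c(1, 1)))$or, 1)
  # spec'd orientation example: higher-exposure row first
  expect_equal(odds_ratio(rbind(c(24, 28), c(6, 49)))$or, 7)
  # scaling all cells leaves the OR unchanged and narrows the CI
  o1 <- odds_ratio(rbind(c(24, 28), c(6, 49)))
  o10 <- odds_ratio(10 * rbind(c(24, 28), c(6, 49)))
  expect_equal(o10$or, o1$or)
  expect_lt(diff(log(o10$ci)), diff(log(o1$ci)))
  # Woolf CI closed form
  se <- sqrt(1 / 24 + 1 / 28 + 1 / 6 + 1 / 49)
  expect_equal(o1$ci, exp(log(7) + c(-1, 1) * stats::qnorm(0.975) * se))
  # zero cell: Haldane-Anscombe correction, flagged
  oz <- odds_ratio(rbind(c(0, 10), c(5, 5)))
  expect_true(oz$corrected)
  expect_equal(oz$or, (0.5 * 5.5) / (10.5 * 5.5))
  # zero marginal line: undefined
  ou <- odds_ratio(rbind(c(0, 0), c(5, 5)))
  expect_false(ou$defined)
})

test_that("case_control assembles overall and pairwise blocks coherently", {
  cc <- case_control(table3_counts())
  expect_s3_class(cc, "cpr_case_control")
  expect_equal(round(cc$green_vs_red$cramers_v$v, 2), 0.55)
  expect_equal(cc$green_vs_red$cramers_v$label, "Large")
  expect_equal(nrow(cc$amber_vs_red$pairwise), 3)
  # the green-vs-red T1 vs T2 OR is the worked cross-product example
  expect_equal(cc$green_vs_red$pairwise$odds_ratio[3], 7)
  expect_output(print(cc), "Cramer's V = 0.55")
})
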