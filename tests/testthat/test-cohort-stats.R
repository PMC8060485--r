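test_that("Woolf odds ratios reproduce the published 2x2 results", {
  # velocity x collateral: 11 fast-poor, 3 slow-poor, 8 fast-good, 14 slow-good
  or <- odds_ratio_woolf(11, 3, 8, 14)
  expect_equal(or$odds_ratio, 154 / 24)
  expect_equal(round(or$odds_ratio, 2), 6.42)
  expect_equal(round(or$ci_low, 2), 1.37)
  expect_equal(round(or$ci_high, 2), 30.05)
  expect_equal(or$method, "woolf")

  # two-vein absence x outcome (good outcome as the case row)
  or5 <- odds_ratio_woolf(1, 24, 6, 5)
  expect_equal(or5$odds_ratio, 5 / 144)
  expect_equal(round(or5$ci_low, 3), 0.003)
  expect_equal(round(or5$ci_high, 2), 0.36)

  expect_equal(odds_ratio_woolf(1, 1, 1, 1)$odds_ratio, 1)
  expect_error(odds_ratio_woolf(0, 0, 0, 0), "empty")
  expect_error(odds_ratio_woolf(1, -2, 3, 4), "non-negative")
})

test_that("zero cells trigger the Haldane-Anscombe correction", {
  or <- odds_ratio_woolf(5, 0, 3, 7)
  expect_equal(or$method, "woolf_haldane")
  expect_equal(or$odds_ratio, (5.5 * 7.5) / (0.5 * 3.5))  # recomputed by hand
  se <- sqrt(1 / 5.5 + 1 / 0.5 + 1 / 3.5 + 1 / 7.5)
  expect_equal(or$ci_low, exp(log(or$odds_ratio) - qnorm(0.975) * se))
})

test_that("the exposure-flip reciprocal identity holds on uncorrected tables", {
  set.seed(8)
  for (i in 1:30) {
    cells <- random_2x2(60) + 1L  # all positive -> no correction
    o1 <- odds_ratio_woolf(cells[1], cells[2], cells[3], cells[4])
    o2 <- odds_ratio_woolf(cells[2], cells[1], cells[4], cells[3])
    expect_equal(o1$odds_ratio * o2$odds_ratio, 1)
  }
})

test_that("Pearson chi-square matches the closed form and degenerate tables are flagged", {
  a <- 8; b <- 14; cc <- 11; d <- 3
  ts <- association_test_2x2(a, b, cc, d, mode = "pearson")
  n <- a + b + cc + d
  closed <- n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  expect_equal(ts$statistic, closed)
  expect_equal(ts$p_value, pchisq(closed, 1, lower.tail = FALSE))

  ind <- association_test_2x2(10, 10, 10, 10, mode = "pearson")
  expect_equal(ind$statistic, 0)
  expect_equal(ind$p_value, 1)

  degen <- association_test_2x2(0, 0, 5, 7)
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 1)

  # auto mode switches to Fisher when an expected count drops below 5
  expect_equal(association_test_2x2(1, 9, 2, 8)$method, "fisher")
  expect_equal(association_test_2x2(20, 20, 20, 25)$method, "pearson")
  # all expected counts exactly 5 stay with Pearson (strict < 5 rule)
  expect_equal(association_test_2x2(1, 9, 9, 1)$method, "pearson")
})

test_that("Fisher p-values agree with exhaustive hypergeometric enumeration", {
  expect_equal(association_test_2x2(1, 9, 9, 1, mode = "fisher")$p_value,
               fisher_p_enum(1, 9, 9, 1), tolerance = 1e-12)
  set.seed(21)
  for (i in 1:100) {
    cells <- random_2x2(40)
    p_impl <- association_test_2x2(cells[1], cells[2], cells[3], cells[4],
                                   mode = "fisher")$p_value
    p_enum <- fisher_p_enum(cells[1], cells[2], cells[3], cells[4])
    expect_equal(p_impl, p_enum, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney exact p-values match full permutation enumeration", {
  expect_equal(group_compare_continuous(c(1, 2), c(3, 4))$p_value,
               mw_p_enum(c(1, 2), c(3, 4)))
  expect_equal(mw_p_enum(c(1, 2), c(3, 4)), 1 / 3)
  set.seed(13)
  for (i in 1:25) {
    m <- sample(2:5, 1)
    n <- sample(2:5, 1)
    x <- round(rnorm(m), 3)   # continuous -> tie-free
    y <- round(rnorm(n), 3)
    r <- group_compare_continuous(x, y)
    expect_equal(r$method, "mann_whitney_exact")
    expect_equal(r$p_value, mw_p_enum(x, y), tolerance = 1e-12)
  }
  # identical samples give p = 1 (forced through the normal path by ties)
  same <- group_compare_continuous(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
})

test_that("t mode is the pooled-variance Student test with degenerate guard", {
  x <- c(1.2, 3.1, 2.5, 4.0)
  y <- c(2.2, 5.1, 3.9)
  r <- group_compare_continuous(x, y, mode = "t")
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(r$statistic, unname(ref$statistic))
  expect_equal(r$p_value, ref$p.value)
  expect_error(group_compare_continuous(rep(1, 3), rep(2, 4), mode = "t"),
               class = "cvf_degenerate_test")
})

test_that("logistic regression on an all-positive 2x2 reproduces the cross-product odds ratio", {
  set.seed(34)
  for (i in 1:20) {
    cells <- random_2x2(60) + 1L
    a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
    outcome <- rep(c(1, 1, 0, 0), c(a, b, cc, d))
    exposed <- rep(c(1, 0, 1, 0), c(a, b, cc, d))
    fit <- logistic_regression(outcome, exposed)
    expect_equal(unname(fit$odds_ratio[2]), (a * d) / (b * cc),
                 tolerance = 1e-6)
  }
})

test_that("logistic intercept-only, Wald intervals and separation behave as specified", {
  y <- rep(c(1, 0), c(25, 75))
  fit <- logistic_regression(y)
  expect_equal(unname(fit$coefficients[1]), log(0.25 / 0.75),
               tolerance = 1e-8)
  expect_equal(unname(fit$ci_low[1]),
               exp(unname(fit$coefficients[1] - qnorm(0.975) * fit$se[1])))

  # a perfectly separated predictor must raise, not return divergent betas
  xs <- c(rnorm(20, -3), rnorm(20, 3))
  ys <- as.integer(xs > 0)
  expect_error(logistic_regression(ys, xs), class = "cvf_separation")
  expect_error(logistic_regression(rep(1, 10)), "both classes")
  expect_error(logistic_regression(c(0, 1), matrix(rnorm(8), 2)),
               "observations")
})

test_that("count-percentage and median-IQR formatting follow the table conventions", {
  expect_equal(fmt_count_pct(8, 22), "8 (36%)")
  expect_equal(fmt_count_pct(11, 14), "11 (79%)")
  expect_equal(fmt_count_pct(0, 17), "0 (0%)")
  expect_equal(fmt_count_pct(6, 11), "6 (55%)")  # half-away rounding, 54.5 -> 55
  expect_equal(round_half_away(c(0.5, 1.5, 2.5, -0.5)), c(1, 2, 3, -1))
  expect_equal(fmt_median_iqr(c(1, 2, 3, 4, 100)), "3.0 (2.0-4.0)")
  expect_equal(fmt_median_iqr(numeric(0)), "-")
})
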