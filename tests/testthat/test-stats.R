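# Cohort statistics: group comparisons, recovery tests, correlation,
# stepwise selection, bootstrap medians.

test_that("group_compare handles identical groups and adjusts pairwise p", {
  g <- rep(c("a", "b", "c"), each = 4)
  same <- group_compare(rep(7, 12), g)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  set.seed(1)
  gc <- group_compare(rnorm(12), g)
  expect_identical(nrow(gc$pairwise), 3L)             # Bonferroni factor 3
  expect_true(all(gc$pairwise$p_adj >= gc$pairwise$p_raw))
  expect_equal(gc$pairwise$p_adj,
               pmin(gc$pairwise$p_raw * 3, 1))
  expect_error(group_compare(1:3, rep("a", 3)), "two non-empty groups")
})

test_that("chi-squared path matches the hand-computed 2x2 statistic", {
  # contingency [[10,0],[0,10]]: sum (O-E)^2/E = 20 without continuity
  # correction
  vals <- rep(c(0, 1), each = 10)
  grp <- rep(c("a", "b"), each = 10)
  gc <- group_compare(vals, grp, kind = "categorical")
  expect_equal(gc$statistic, 20)
  expect_identical(nrow(gc$pairwise), 1L)
})

test_that("recovery-to-baseline test follows the exact enumeration convention", {
  # all-positive tied sample, n = 10: two-sided exact p = 2^-9
  r <- baseline_recovery_test(rep(5, 10))
  expect_equal(r$p_value, 2^-9)
  expect_equal(r$median, 5)

  # symmetric sample around zero: no evidence of an offset
  x <- c(-4, -3, -2, -1, 1, 2, 3, 4) * 1.5
  expect_gt(baseline_recovery_test(x)$p_value, 0.9)

  # degenerate inputs flagged, not raised
  expect_true(baseline_recovery_test(0)$degenerate)
  expect_true(is.na(baseline_recovery_test(c(0, 0, 0))$p_value))
  one <- baseline_recovery_test(3)
  expect_true(one$degenerate)
})

test_that("spearman correlation: monotone limits, ties, degenerate input", {
  x <- c(1, 4, 9, 12, 20)
  expect_equal(correlate(x, exp(x / 10))$rho, 1)
  expect_equal(correlate(x, -x^3)$rho, -1)
  d <- correlate(rep(1, 5), 1:5)
  expect_true(d$degenerate)
  expect_true(is.na(d$rho))
  expect_error(correlate(1:2, 1:2), "at least 3")
})

test_that("forward stepwise rejects noise and recovers a planted signal", {
  # pure-noise candidate pair: the per-candidate entry test implies a null
  # selection rate of about 1 - 0.95^k, so with two candidates the model
  # stays intercept-only in >= 90% of seeded trials
  null_hits <- 0L
  for (i in 1:100) {
    set.seed(i)
    y <- rnorm(60)
    cand <- data.frame(u = rnorm(60), v = rnorm(60))
    m <- stepwise_lm(y, cand, alpha_in = 0.05)
    if (length(m$selected) == 0L) null_hits <- null_hits + 1L
  }
  expect_gte(null_hits, 90L)

  # y = 2x + noise among 10 decoys: x enters first with slope ~2
  set.seed(7)
  x <- rnorm(100)
  cand <- data.frame(x = x, matrix(rnorm(100 * 10), ncol = 10))
  y <- 2 * x + rnorm(100, 0, 0.1)
  m <- stepwise_lm(y, cand)
  expect_identical(m$selected[1L], "x")
  expect_true(m$coefficients[["x"]] > 1.9 && m$coefficients[["x"]] < 2.1)
})

test_that("collinear candidates are skipped and leave the model unchanged", {
  set.seed(8)
  x <- rnorm(50)
  y <- 1.5 * x + rnorm(50, 0, 0.3)
  ref <- stepwise_lm(y, data.frame(x = x))
  expect_warning(
    dup <- stepwise_lm(y, data.frame(x = x, x_copy = x)), "collinear")
  expect_identical(dup$selected, "x")
  expect_equal(dup$coefficients, ref$coefficients)
})

test_that("bootstrap median CI is seeded and consistent with order statistics", {
  expect_error(median_ci(3), "n >= 2")
  const <- median_ci(rep(4.2, 20), seed = 1)
  expect_equal(const$ci_lower, 4.2)
  expect_equal(const$ci_upper, 4.2)

  set.seed(42)
  x <- round(rnorm(11, 50, 8), 1)
  a <- median_ci(x, seed = 5)
  b <- median_ci(x, seed = 5)
  expect_identical(a, b)
  # bootstrap CI nested inside the conservative exact order-statistic CI
  os <- oracle_median_orderstat_ci(x)
  expect_gte(a$ci_lower, os[1L])
  expect_lte(a$ci_upper, os[2L])
  expect_true(a$ci_lower <= a$median && a$median <= a$ci_upper)
})

test_that("paired pre/post comparison is antisymmetric and exact at small n", {
  pre <- c(10, 12, 9, 14, 11, 13, 10, 12, 15, 9, 11, 13, 12)
  expect_true(paired_pre_post(pre, pre)$degenerate)

  shifted <- paired_pre_post(pre, pre - 10)
  expect_equal(shifted$p_value, 2 * 2^-13)   # exact sign enumeration, n = 13
  expect_equal(shifted$median_diff, -10)

  set.seed(9)
  post <- pre + rnorm(13)
  ab <- paired_pre_post(pre, post)
  ba <- paired_pre_post(post, pre)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$median_diff, -ba$median_diff)
})
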