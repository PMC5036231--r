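# Exact conditional inference for 2x2 tables: agreement with independent
# oracles and the distributional invariances of conditional odds-ratio
# inference.

swim_tab <- table2x2(36, 2, 68, 18)
work_tab <- table2x2(6, 32, 3, 83)

test_that("conditional MLE and central CI agree with fisher.test", {
  tabs <- list(swim_tab, work_tab, table2x2(5, 1, 2, 7), table2x2(10, 10, 3, 17),
               table2x2(1, 9, 4, 6), table2x2(12, 4, 9, 11))
  for (tb in tabs) {
    ft <- fisher.test(matrix(c(tb$a, tb$c, tb$b, tb$d), 2, 2))
    # fisher.test's own optimiser is only accurate to ~1e-3 on flat tails
    expect_equal(conditional_mle_or(tb), unname(ft$estimate), tolerance = 1e-3)
    expect_equal(exact_or_ci(tb, method = "central"), as.numeric(ft$conf.int),
                 tolerance = 1e-2)
    expect_equal(fisher_exact_p(tb), ft$p.value, tolerance = 1e-9)
    expect_equal(fisher_exact_p(tb, "greater"),
                 fisher.test(matrix(c(tb$a, tb$c, tb$b, tb$d), 2, 2),
                             alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("central CI endpoints carry exactly alpha/2 conditional tail probability", {
  # the defining property, checked against brute-force table probabilities
  for (tb in list(table2x2(36, 2, 68, 18), table2x2(6, 32, 3, 83),
                  table2x2(5, 1, 2, 7), table2x2(10, 10, 3, 17))) {
    ci <- exact_or_ci(tb, level = 0.95, method = "central")
    pr_lo <- bf_probs(tb$n_cases, tb$n_controls, tb$n_exposed, ci[1])
    expect_equal(sum(pr_lo$p[pr_lo$x >= tb$a]), 0.025, tolerance = 1e-7)
    pr_hi <- bf_probs(tb$n_cases, tb$n_controls, tb$n_exposed, ci[2])
    expect_equal(sum(pr_hi$p[pr_hi$x <= tb$a]), 0.025, tolerance = 1e-7)
  }
})

test_that("exchangeable rows give an odds ratio of exactly 1", {
  expect_equal(conditional_mle_or(table2x2(2, 2, 2, 2)), 1, tolerance = 1e-8)
  ci <- exact_or_ci(table2x2(2, 2, 2, 2))
  expect_lt(ci[1], 1)
  expect_gt(ci[2], 1)
  expect_equal(fisher_exact_p(table2x2(1, 1, 1, 1)), 1)
})

test_that("swapping exposure labels inverts the odds ratio and reciprocates the CI", {
  for (tb in list(swim_tab, table2x2(7, 3, 2, 9), table2x2(4, 11, 8, 5))) {
    sw <- table2x2(tb$b, tb$a, tb$d, tb$c)
    expect_equal(conditional_mle_or(sw), 1 / conditional_mle_or(tb), tolerance = 1e-6)
    for (method in c("minlike", "central")) {
      ci <- exact_or_ci(tb, method = method)
      ci_sw <- exact_or_ci(sw, method = method)
      expect_equal(ci_sw, rev(1 / ci), tolerance = 1e-6)
    }
  }
})

test_that("transposing the case/exposure axes changes neither OR nor Fisher p", {
  for (tb in list(swim_tab, work_tab, table2x2(3, 8, 6, 2))) {
    tr <- table2x2(tb$a, tb$c, tb$b, tb$d)
    expect_equal(conditional_mle_or(tr), conditional_mle_or(tb), tolerance = 1e-6)
    expect_equal(fisher_exact_p(tr), fisher_exact_p(tb), tolerance = 1e-10)
  }
})

test_that("zero cells give boundary estimates and one-sided intervals", {
  tb0 <- table2x2(0, 10, 5, 5)
  expect_identical(conditional_mle_or(tb0), 0)
  ci0 <- exact_or_ci(tb0)
  expect_identical(ci0[1], 0)
  expect_true(is.finite(ci0[2]))
  tbI <- table2x2(10, 0, 5, 5)
  expect_identical(conditional_mle_or(tbI), Inf)
  ciI <- exact_or_ci(tbI)
  expect_identical(ciI[2], Inf)
  expect_gt(ciI[1], 0)
  expect_error(conditional_mle_or(table2x2(0, 0, 3, 4)), "margin")
})

test_that("both interval orderings bracket the conditional MLE", {
  set.seed(404)
  for (i in 1:40) {
    cnt <- rpois(4, 6) + c(1, 0, 0, 1)
    tb <- table2x2(cnt[1], cnt[2], cnt[3], cnt[4])
    or <- conditional_mle_or(tb)
    if (!is.finite(or) || or == 0) next
    for (method in c("minlike", "central")) {
      ci <- exact_or_ci(tb, method = method)
      expect_lte(ci[1], or)
      expect_gte(ci[2], or)
    }
  }
})

test_that("the minlike CI excludes 1 exactly when the two-sided exact p is below alpha", {
  set.seed(99)
  for (i in 1:60) {
    cnt <- rpois(4, 5) + 1
    tb <- table2x2(cnt[1], cnt[2], cnt[3], cnt[4])
    p <- fisher_exact_p(tb)
    if (abs(p - 0.05) < 1e-9) next
    ci <- exact_or_ci(tb, level = 0.95, method = "minlike")
    excludes_one <- ci[1] > 1 || ci[2] < 1
    expect_identical(excludes_one, p < 0.05,
                     info = sprintf("table (%d,%d,%d,%d)", cnt[1], cnt[2], cnt[3], cnt[4]))
  }
})

test_that("exact_or bundles point, interval and p consistently", {
  res <- exact_or(work_tab)
  expect_s3_class(res, "or_estimate")
  expect_equal(res$or_point, conditional_mle_or(work_tab))
  expect_equal(c(res$ci_low, res$ci_high), exact_or_ci(work_tab))
  expect_equal(res$p_value, fisher_exact_p(work_tab))
  expect_false(res$boundary)
  expect_true(exact_or(table2x2(10, 0, 5, 5))$boundary)
})

test_that("invalid tables are rejected", {
  expect_error(table2x2(-1, 2, 3, 4), "non-negative")
  expect_error(table2x2(1.5, 2, 3, 4), "non-negative")
  expect_error(exact_or_ci(table2x2(1, 2, 3, 4), level = 1.2), "level")
})
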