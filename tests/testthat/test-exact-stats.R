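# Exact contingency inference: enumeration-oracle equivalence, odds
# ratios and confidence intervals against the printed audit values, the
# chi-squared switch, Bonferroni correction.

test_that("2x2 p-values equal the hypergeometric enumeration oracle", {
  expect_equal(fisher_2x2(matrix(c(1, 1, 1, 1), 2)), 1.0)
  t2 <- matrix(c(3, 1, 1, 3), 2, byrow = TRUE)
  expect_equal(fisher_2x2(t2), oracle_fisher_2x2(t2), tolerance = 1e-10)
  set.seed(33)
  for (rep_i in 1:60) {
    tab <- matrix(rpois(4, sample(1:8, 1)), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    for (alt in c("two_sided", "greater", "less")) {
      expect_equal(fisher_2x2(tab, alt), oracle_fisher_2x2(tab, alt),
        tolerance = 1e-9, info = paste(c(tab, alt), collapse = ","))
    }
  }
  expect_warning(p <- fisher_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
    "degenerate")
  expect_equal(p, 1)
})

test_that("one-sided tails are at least the observed-table probability;
           two-sided at least the larger of neither tail deficit", {
  set.seed(91)
  for (rep_i in 1:40) {
    tab <- matrix(rpois(4, 4), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p_obs <- dhyper(tab[1, 1], sum(tab[1, ]), sum(tab[2, ]),
      sum(tab[, 1]))
    expect_gte(fisher_2x2(tab, "greater") + 1e-12, p_obs)
    expect_gte(fisher_2x2(tab, "less") + 1e-12, p_obs)
    expect_gte(fisher_2x2(tab) + 1e-12, p_obs)
  }
})

test_that("conditional-MLE odds ratio matches direct likelihood
           maximization and the printed audit tables", {
  afr_select <- matrix(c(25, 12, 661, 1843), 2, byrow = TRUE)
  expect_equal(round(conditional_mle_or(afr_select), 1), 5.8)
  expect_lt(fisher_2x2(afr_select), 1e-6)
  afr_full14 <- matrix(c(89, 37, 661, 1843), 2, byrow = TRUE)
  expect_equal(round(conditional_mle_or(afr_full14), 1), 6.7)
  afr_full20 <- matrix(c(94, 63, 661, 1843), 2, byrow = TRUE)
  expect_equal(round(conditional_mle_or(afr_full20), 1), 4.2)

  expect_equal(conditional_mle_or(matrix(c(3, 3, 7, 7), 2)), 1.0,
    tolerance = 1e-6)
  set.seed(55)
  for (rep_i in 1:20) {
    tab <- matrix(rpois(4, 6) + 1, 2)
    expect_equal(conditional_mle_or(tab), oracle_cmle_or(tab),
      tolerance = 1e-4, info = paste(tab, collapse = ","))
  }
})

test_that("exact odds-ratio intervals bracket the MLE, widen with level,
           and reproduce the printed interval", {
  afr_select <- matrix(c(25, 12, 661, 1843), 2, byrow = TRUE)
  ci <- exact_or_ci(afr_select)
  expect_equal(round(unname(ci), 1), c(2.8, 12.8))
  ci14 <- exact_or_ci(matrix(c(89, 37, 661, 1843), 2, byrow = TRUE))
  expect_equal(round(unname(ci14), 1), c(4.5, 10.2))
  ci20 <- exact_or_ci(matrix(c(94, 63, 661, 1843), 2, byrow = TRUE))
  expect_equal(round(unname(ci20), 1), c(3.0, 5.9))

  balanced <- matrix(c(1, 1, 1, 1), 2)
  cib <- exact_or_ci(balanced)
  expect_lt(cib[1], 1)
  expect_gt(cib[2], 1)

  tab <- matrix(c(8, 3, 4, 9), 2, byrow = TRUE)
  or <- conditional_mle_or(tab)
  widths <- vapply(c(0.8, 0.9, 0.95, 0.99), function(lv) {
    ci <- exact_or_ci(tab, lv)
    expect_lte(ci[1], or)
    expect_gte(ci[2], or)
    log(ci[2]) - log(ci[1])
  }, 0)
  expect_true(all(diff(widths) > 0))
  # the interval shrinks toward the MLE as the level drops (discreteness
  # leaves a residual gap that still brackets the estimate)
  tight <- exact_or_ci(tab, 0.001)
  expect_lt(log(tight[2]) - log(tight[1]), widths[1] / 2)
  expect_lte(tight[1], or)
  expect_gte(tight[2], or)
})

test_that("the omnibus switches to chi-squared only when all expected
           counts are large, and matches enumeration when exact", {
  prop <- matrix(50, 5, 2)
  res <- omnibus_rxc(prop)
  expect_equal(res$method, "chisq")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  set.seed(66)
  for (rep_i in 1:6) {
    tab <- matrix(rpois(10, 2), 5, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    res <- omnibus_rxc(tab)
    expect_equal(res$method, "exact")
    keep <- rowSums(tab) > 0
    expect_equal(res$p_value, oracle_rxc_p(tab[keep, , drop = FALSE]),
      tolerance = 1e-7, info = paste(tab, collapse = ","))
  }
  expect_error(omnibus_rxc(matrix(0, 5, 2)), "all-zero")
})

test_that("a planted heavily skewed population drives the omnibus below
           the corrected threshold and is flagged in follow-up", {
  aff <- c(AFR = 25, AMR = 3, EAS = 4, EUR = 0, SAS = 5)
  cohort <- c(AFR = 661, AMR = 347, EAS = 504, EUR = 503, SAS = 489)
  ledger <- new_test_ledger()
  res <- ancestry_skew_tests(aff, cohort, ledger = ledger)
  expect_lt(res$omnibus$p_value, 2.2e-4)
  expect_equal(ledger$n, 6L)  # omnibus + 5 follow-ups
  afr <- res$per_population[res$per_population$ancestry == "AFR", ]
  expect_lt(afr$p, 2.2e-4)
  expect_gt(afr$odds_ratio, 1)
})

test_that("the Monte Carlo fallback records its method and is
           deterministic under its fixed seed", {
  tab <- matrix(c(12, 3000, 2, 3000, 1, 3000, 0, 3000, 3, 3000), 5, 2,
    byrow = TRUE)
  r1 <- omnibus_rxc(tab, enumeration_bound = 100, B = 1e5)
  r2 <- omnibus_rxc(tab, enumeration_bound = 100, B = 1e5)
  expect_equal(r1$method, "montecarlo")
  expect_identical(r1$p_value, r2$p_value)
})

test_that("Bonferroni threshold", {
  # 0.05 / 222 = 2.2522e-4, printed as 2.2e-4 (truncated to 2 figures)
  expect_equal(bonferroni(0.05, 222), 0.05 / 222)
  expect_lt(abs(bonferroni(0.05, 222) - 2.2e-4), 1e-5)
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_equal(bonferroni(0.05, 5), 0.01)
})

test_that("the conditional MLE approaches the cross-product ratio as
           cells grow", {
  base <- matrix(c(6, 3, 4, 8), 2, byrow = TRUE)
  cpr <- (base[1, 1] * base[2, 2]) / (base[1, 2] * base[2, 1])
  devs <- vapply(c(1, 10, 100), function(k) {
    abs(conditional_mle_or(base * k) - cpr)
  }, 0)
  expect_true(all(diff(devs) < 0))
  expect_lt(devs[3], 0.01)
})
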