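# Exact and asymptotic contingency-table inference: 2x2 Fisher tests with
# conditional-MLE odds ratios and exact confidence intervals, the 5x2
# omnibus with the chi-squared switch, Bonferroni correction, and the
# test ledger that counts every test actually performed.

.as_table <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x) || any(x < 0) || any(x != round(x))) {
    stop("contingency table must hold non-negative integers")
  }
  storage.mode(x) <- "integer"
  x
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-values use the probability-mass criterion (the sum of
#' fixed-margin table probabilities no larger than the observed table's);
#' one-sided p-values are exact hypergeometric tails. A degenerate margin
#' yields p = 1 with a warning.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative "two_sided", "greater" or "less".
#' @return The exact p-value.
#' @export
fisher_2x2 <- function(table, alternative = c("two_sided", "greater",
                                              "less")) {
  alternative <- match.arg(alternative)
  x <- .as_table(table)
  stopifnot(all(dim(x) == 2L))
  if (any(rowSums(x) == 0L) || any(colSums(x) == 0L)) {
    warning("degenerate margin: p = 1", call. = FALSE)
    return(1)
  }
  alt <- c(two_sided = "two.sided", greater = "greater",
    less = "less")[[alternative]]
  stats::fisher.test(x, alternative = alt)$p.value
}

#' Conditional maximum-likelihood odds ratio of a 2x2 table
#'
#' The maximizer of the noncentral hypergeometric conditional likelihood
#' (0 or Inf when a relevant cell is empty).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return The conditional-MLE odds ratio.
#' @export
conditional_mle_or <- function(table) {
  x <- .as_table(table)
  stopifnot(all(dim(x) == 2L))
  unname(stats::fisher.test(x)$estimate)
}

#' Exact confidence interval for the odds ratio of a 2x2 table
#'
#' Bounds solve the noncentral hypergeometric tail equations at
#' `(1 - level) / 2` on each side; the interval contains the conditional
#' MLE, and is one-sided unbounded when a cell is zero.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param level Confidence level in (0, 1), default 0.95.
#' @return Numeric `c(ci_low, ci_high)`.
#' @export
exact_or_ci <- function(table, level = 0.95) {
  stopifnot(level > 0, level < 1)
  x <- .as_table(table)
  stopifnot(all(dim(x) == 2L))
  ci <- stats::fisher.test(x, conf.level = level)$conf.int
  c(ci_low = ci[1L], ci_high = ci[2L])
}

#' Omnibus r x 2 test with the chi-squared switch
#'
#' When every expected count exceeds `chisq_expected` (40, matching the
#' audit protocol) a Pearson chi-squared test is used; otherwise the exact
#' conditional test (full enumeration over fixed-margin tables) when the
#' table total is at most `enumeration_bound`, else a fixed-seed Monte
#' Carlo estimate. The method actually used is recorded.
#'
#' @param table r x c matrix of non-negative integer counts (r x 2 in the
#'   audit).
#' @param chisq_expected Expected-count threshold for the chi-squared
#'   switch.
#' @param enumeration_bound Largest table total for exact enumeration.
#' @param B Monte Carlo resamples.
#' @param mc_seed Fixed seed for the Monte Carlo fallback.
#' @return list(p_value, method = "chisq"|"exact"|"montecarlo",
#'   statistic = chi-squared statistic or NA).
#' @export
omnibus_rxc <- function(table, chisq_expected = 40,
                        enumeration_bound = 5000, B = 1e6,
                        mc_seed = 20150615L) {
  x <- .as_table(table)
  if (sum(x) == 0L) stop("all-zero contingency table")
  x <- x[rowSums(x) > 0L, colSums(x) > 0L, drop = FALSE]
  if (any(dim(x) < 2L)) {
    return(list(p_value = 1, method = "degenerate", statistic = NA_real_))
  }
  expected <- outer(rowSums(x), colSums(x)) / sum(x)
  if (all(expected > chisq_expected)) {
    ct <- suppressWarnings(stats::chisq.test(x, correct = FALSE))
    return(list(p_value = unname(ct$p.value), method = "chisq",
      statistic = unname(ct$statistic)))
  }
  if (sum(x) <= enumeration_bound) {
    p <- stats::fisher.test(x, workspace = 2e8)$p.value
    return(list(p_value = p, method = "exact", statistic = NA_real_))
  }
  p <- with_seed(mc_seed,
    stats::fisher.test(x, simulate.p.value = TRUE, B = B)$p.value)
  list(p_value = p, method = "montecarlo", statistic = NA_real_)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise significance level.
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni <- function(alpha, m) {
  stopifnot(m >= 1)
  alpha / m
}

#' A ledger counting every statistical test performed in a run
#'
#' The multiple-testing correction divides by the number of tests actually
#' performed (one omnibus per non-zero bar plus one follow-up per
#' population when the omnibus is significant), so the ledger is the
#' source of `m` for [bonferroni()].
#'
#' @return An environment with `n` (count) and `tests` (descriptions).
#' @export
new_test_ledger <- function() {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  env$tests <- character(0)
  class(env) <- "test_ledger"
  env
}

#' @rdname new_test_ledger
#' @param ledger A test ledger.
#' @param description What was tested.
#' @export
record_test <- function(ledger, description) {
  ledger$n <- ledger$n + 1L
  ledger$tests <- c(ledger$tests, description)
  invisible(ledger$n)
}

#' Ancestry-composition skew tests for one set of affected individuals
#'
#' Omnibus r x 2 test of the affected-individual ancestry composition
#' against the cohort composition, followed (when the omnibus p is below
#' `follow_alpha`) by per-population one-sided 2x2 tests of the
#' population's affected count against its cohort count with the other
#' populations pooled, plus two-sided conditional-MLE odds ratios with
#' exact confidence intervals. Every test is recorded in `ledger`.
#'
#' @param affected_counts Named vector: affected individuals per ancestry.
#' @param cohort_counts Named vector: cohort individuals per ancestry.
#' @param ledger A [new_test_ledger()] (tests are appended).
#' @param follow_alpha Nominal level triggering per-population follow-ups.
#' @param label Bar label for the ledger.
#' @return list(omnibus = omnibus result, per_population = data.frame with
#'   p, odds_ratio, ci_low, ci_high per ancestry (NULL when no follow-up)).
#' @export
ancestry_skew_tests <- function(affected_counts, cohort_counts,
                                ledger = new_test_ledger(),
                                follow_alpha = 0.05, label = "") {
  ancs <- names(cohort_counts)
  aff <- affected_counts[ancs]
  aff[is.na(aff)] <- 0L
  if (sum(aff) == 0L) {
    return(list(omnibus = NULL, per_population = NULL))
  }
  tab <- cbind(affected = as.integer(aff),
    cohort = as.integer(cohort_counts))
  rownames(tab) <- ancs
  omni <- omnibus_rxc(tab)
  record_test(ledger, paste0("omnibus ", label))
  per <- NULL
  if (omni$p_value < follow_alpha) {
    per <- do.call(rbind, lapply(ancs, function(a) {
      t2 <- matrix(c(aff[[a]], sum(aff) - aff[[a]],
        cohort_counts[[a]], sum(cohort_counts) - cohort_counts[[a]]),
        2L, byrow = TRUE)
      record_test(ledger, paste0("follow-up ", label, " ", a))
      ci <- exact_or_ci(t2)
      data.frame(ancestry = a,
        p = fisher_2x2(t2, "greater"),
        odds_ratio = conditional_mle_or(t2),
        ci_low = ci[[1L]], ci_high = ci[[2L]],
        stringsAsFactors = FALSE)
    }))
  }
  list(omnibus = omni, per_population = per)
}
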