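# Burden detection: mechanism calls, oracle equivalence, monotonicity,
# set nesting, yearly maxima, rates.

# hand-built micro cohort: phased GT strings indexed [variant, sample]
micro_cohort <- function(gt_rows, samples) {
  ids <- names(gt_rows)
  v <- parse_key(ids)
  gt <- do.call(rbind, gt_rows)
  rownames(gt) <- ids
  colnames(gt) <- samples$sample
  list(variants = v, gt = gt, samples = samples)
}

micro_panel <- data.frame(
  gene = c("GENE_A", "GENE_X"), chrom = c("chr1", "chrX"),
  start = c(100L, 100L), end = c(1000L, 1000L),
  inheritance = c("AR", "XL"), stringsAsFactors = FALSE)

test_that("hom, hemi and phased comphet configurations are called correctly", {
  samples <- data.frame(sample = c("S1", "S2", "S3", "S4"),
    sex = c("female", "male", "female", "female"),
    ancestry = "EUR", stringsAsFactors = FALSE)
  cohort <- micro_cohort(list(
    "chr1:200:A:G" = c("1|1", "0|0", "1|0", "1|0"),
    "chr1:300:C:T" = c("0|0", "0|0", "0|1", "1|0"),
    "chrX:200:G:A" = c("0|0", "1|1", "0|0", "0|0")), samples)
  calls <- detect_affected(cohort, cohort$variants$id, micro_panel)
  expect_equal(calls$mechanism[calls$sample == "S1"], "hom")
  expect_equal(calls$mechanism[calls$sample == "S2"], "hemi")
  # S3: alt|ref + ref|alt in one gene -> comphet; S4: both alt|ref -> cis
  expect_equal(calls$mechanism[calls$sample == "S3"], "comphet")
  expect_equal(strsplit(calls$variants[calls$sample == "S3"], ",")[[1]],
    c("chr1:200:A:G", "chr1:300:C:T"))
  expect_false("S4" %in% calls$sample)
})

test_that("all phased two-variant configurations match brute force", {
  samples <- data.frame(sample = "S", sex = "female", ancestry = "EUR",
    stringsAsFactors = FALSE)
  gts <- c("0|0", "0|1", "1|0", "1|1")
  for (g1 in gts) for (g2 in gts) {
    cohort <- micro_cohort(list("chr1:200:A:G" = g1,
      "chr1:300:C:T" = g2), samples)
    calls <- detect_affected(cohort, cohort$variants$id, micro_panel)
    want <- oracle_detect(cohort, cohort$variants$id, micro_panel)
    expect_equal(nrow(calls), nrow(want), info = paste(g1, g2))
    if (nrow(want) > 0) {
      expect_equal(calls$mechanism, want$mechanism, info = paste(g1, g2))
    }
  }
})

test_that("detection equals the O(samples x variants^2) oracle on random
           fixtures", {
  set.seed(2024)
  panel <- gen_panel(3, 1, seed = 31)
  for (rep_i in 1:5) {
    cohort <- gen_cohort(panel,
      c(AFR = 15, EUR = 15, EAS = 10),
      data.frame(mechanism = c("hom", "comphet", "hemi"),
        ancestry = c("AFR", "EUR", "EAS")),
      seed = 100 + rep_i, background_rate = 0.2,
      background_vars_per_gene = 6L)
    # randomly subset the variant set to exercise set dependence
    ids <- cohort$variants$id
    set_ids <- sample(ids, ceiling(length(ids) * 0.8))
    got <- detect_affected(cohort, set_ids, panel)
    want <- oracle_detect(cohort, set_ids, panel)
    key <- function(d) sort(paste(d$sample, d$gene, d$mechanism))
    expect_equal(key(got), key(want))
  }
})

test_that("adding a variant to a set never decreases the affected count", {
  panel <- gen_panel(2, 1, seed = 5)
  cohort <- gen_cohort(panel, c(AFR = 30, EUR = 30),
    data.frame(mechanism = c("hom", "comphet"), ancestry = c("AFR", "EUR")),
    seed = 6, background_rate = 0.3, background_vars_per_gene = 4L)
  ids <- cohort$variants$id
  set.seed(10)
  n_prev <- -1L
  for (k in c(2, 5, 10, length(ids))) {
    calls <- detect_affected(cohort, ids[seq_len(k)], panel)
    n <- length(unique(calls$sample))
    expect_gte(n, max(n_prev, 0L))
    n_prev <- n
  }
})

test_that("yearly count is the maximum over the year's snapshots", {
  calls <- data.frame(
    sample = c("a", "b", "c", "a", "b", "a"),
    date = c(rep("2016-01-01", 3), rep("2016-06-01", 2), "2017-01-01"),
    stringsAsFactors = FALSE)
  ym <- yearly_max(calls)
  expect_equal(ym$n_affected[ym$year == 2016], 3L)
  expect_equal(ym$n_affected[ym$year == 2017], 1L)
})

test_that("false-positive rate and expected-affected baselines", {
  expect_equal(round(fp_rate(11, 5833), 1), 1.9)
  expect_equal(fp_rate(0, 100), 0)
  expect_equal(round(fp_rate(8, 1096), 1), 7.3)
  expect_true(is.na(fp_rate(3, 0)))
  expect_equal(expected_affected(2504, 1 / 3200), 2504 / 3200)
  expect_lt(expected_affected(2504, 1 / 3200), 1)
  expect_equal(expected_affected(3200, 1 / 3200), 1)
  expect_equal(expected_affected(0, 1 / 3200), 0)
})

test_that("unphased genotypes are skipped with a warning, or error on
           request", {
  samples <- data.frame(sample = "S", sex = "female", ancestry = "EUR",
    stringsAsFactors = FALSE)
  cohort <- micro_cohort(list("chr1:200:A:G" = "0/1",
    "chr1:300:C:T" = "0|1"), samples)
  expect_warning(calls <- detect_affected(cohort, cohort$variants$id,
    micro_panel), "unphased")
  expect_equal(nrow(calls), 0L)
  expect_error(detect_affected(cohort, cohort$variants$id, micro_panel,
    unphased = "error"), "unphased")
})

test_that("select sets stay nested within full sets end to end", {
  panel <- gen_panel(3, 1, seed = 12)
  cohort <- gen_cohort(panel, c(AFR = 25, EUR = 25),
    data.frame(mechanism = "hom", ancestry = "AFR"), seed = 13)
  carried <- cbind(parse_key(cohort$variants$id)[,
    c("chrom", "pos", "ref", "alt")],
    data.frame(id = cohort$variants$id, category = "P/LP_1", tier = "P"))
  snaps <- gen_snapshot_series(panel,
    dates = c("2016-01-01", "2017-01-01"), dialect = "archive2",
    seed = 14, extra_variants = carried, n_background = 30)
  tl <- build_timelines(snaps$files)
  for (d in unique(tl$date)) {
    snap <- snapshot_at(tl, d)
    sel <- select_variant_set(snap, "select_clinvar")
    full <- select_variant_set(snap, "full_clinvar")
    expect_true(all(sel %in% full))
    aff_sel <- detect_affected(cohort, sel, panel)
    aff_full <- detect_affected(cohort, full, panel)
    expect_true(all(aff_sel$sample %in% aff_full$sample))
  }
})
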