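# Snapshot ingest: key normalization, label maps, review stars, condition
# filter, variant-set selection, timeline round-trip.

test_that("SNVs pass through normalization; the worked indel left-aligns", {
  nv <- normalize_variant("chr1", 100, "A", "G", "AAAAG",
    context_start = 98)
  expect_equal(nv$pos, 100)
  expect_equal(nv$ref, "A")
  expect_equal(nv$alt, "G")

  nv <- normalize_variant("chr1", 5, "TT", "T", "GCATTT")
  expect_equal(nv[, c("pos", "ref", "alt")],
    data.frame(pos = 3L, ref = "AT", alt = "A"))
  expect_error(normalize_variant("chr1", 5, "AA", "A", "GCATTT"),
    "reference mismatch")
})

test_that("normalization matches the brute-force minimal-representation oracle
           and is idempotent", {
  set.seed(421)
  bases <- c("A", "C", "G", "T")
  for (rep_i in 1:40) {
    context <- paste(sample(bases, 12, replace = TRUE), collapse = "")
    pos <- sample(3:9, 1)
    type <- sample(c("del", "ins", "snv"), 1)
    if (type == "del") {
      len <- sample(1:3, 1)
      if (pos + len > nchar(context)) next
      ref <- substr(context, pos, pos + len)
      alt <- substr(context, pos, pos)
    } else if (type == "ins") {
      ref <- substr(context, pos, pos)
      alt <- paste0(ref, paste(sample(bases, sample(1:2, 1),
        replace = TRUE), collapse = ""))
    } else {
      ref <- substr(context, pos, pos)
      alt <- sample(setdiff(bases, ref), 1)
    }
    if (ref == alt) next
    got <- normalize_variant("chr1", pos, ref, alt, context)
    want <- oracle_normalize(pos, ref, alt, context)
    expect_equal(got$pos, want$pos, info = paste(context, pos, ref, alt))
    expect_equal(got$ref, want$ref, info = paste(context, pos, ref, alt))
    expect_equal(got$alt, want$alt, info = paste(context, pos, ref, alt))
    again <- normalize_variant(got$chrom, got$pos, got$ref, got$alt,
      context)
    expect_identical(again$id, got$id)
  }
})

test_that("archive-1 and archive-2 significance maps follow the dialects", {
  expect_equal(map_archive1_class(c("5", "0", "4", "3", "2")),
    c("P", "VUS", "LP", "LB", "B"))
  expect_true(is.na(map_archive1_class("9")))

  expect_equal(map_archive2_class("Pathogenic,_risk_factor"), "P")
  expect_equal(
    map_archive2_class("Conflicting_interpretations_of_pathogenicity"),
    "Conflicting")
  expect_equal(map_archive2_class("Benign/Likely_benign"), "B")
  expect_true(is.na(map_archive2_class("Pathogenic,Benign")))
  expect_true(is.na(map_archive2_class("association")))
})

test_that("Conflicting inference matches the group rule on every subset", {
  tiers <- c("B", "LB", "VUS", "LP", "P")
  group <- c(B = "BLB", LB = "BLB", VUS = "VUS", LP = "PLP", P = "PLP")
  for (mask in 1:31) {
    sub <- tiers[as.logical(bitwAnd(mask, 2^(0:4)))]
    got <- infer_conflicting(sub)
    if (length(unique(group[sub])) >= 2) {
      expect_equal(got, "Conflicting", info = paste(sub, collapse = ","))
    } else {
      expect_false(got == "Conflicting", info = paste(sub, collapse = ","))
      expect_true(got %in% sub ||
        (got == "P" && "P" %in% sub) || (got == "B" && "B" %in% sub))
    }
  }
  expect_equal(infer_conflicting(c("P", "VUS")), "Conflicting")
  expect_equal(infer_conflicting(c("P", "LP")), "P")
  expect_error(infer_conflicting(character(0)), "empty")
})

test_that("review-star grouping follows both archive dialects", {
  expect_equal(map_review_stars("criteria_provided,_single_submitter", 2),
    1L)
  expect_equal(map_review_stars("reviewed_by_expert_panel", 2), 2L)
  expect_equal(map_review_stars("no_assertion_provided", 1), 0L)
  expect_equal(map_review_stars(
    "criteria_provided,_multiple_submitters,_no_conflicts", 2), 2L)
  expect_warning(s <- map_review_stars("garbled_status", 2), "unknown")
  expect_equal(s, 0L)
})

test_that("HGMD label resolution takes the most severe, pairwise", {
  expect_equal(map_hgmd_class(c("DM?", "DM")), "DM")
  expect_equal(map_hgmd_class("DM?"), "DM?")
  severity <- c("DM", "DM?", "DFP", "DP", "R")  # decreasing
  for (i in seq_along(severity)) for (j in seq_along(severity)) {
    expect_equal(map_hgmd_class(c(severity[i], severity[j])),
      severity[min(i, j)], info = paste(i, j))
  }
  expect_true(is.na(suppressMessages(map_hgmd_class("XX"))))
})

test_that("condition filter keeps allowlisted and 'not provided' entries", {
  entries <- data.frame(id = 1:3,
    condition = c("schizophrenia", "not provided", "disorder A"))
  kept <- filter_condition(entries, allowlist = "disorder A")
  expect_equal(kept$id, c(2L, 3L))
  all_np <- data.frame(id = 1:2, condition = "not provided")
  expect_equal(nrow(filter_condition(all_np, character(0))), 2L)
})

test_that("variant sets implement the star and tier rules, with nesting", {
  panel <- gen_panel(3, 0, seed = 8)
  snaps <- gen_snapshot_series(panel,
    dates = c("2016-01-01", "2016-02-01"), dialect = "archive2",
    seed = 8, n_background = 40)
  tl <- build_timelines(snaps$files)
  snap <- snapshot_at(tl, "2016-01-01")
  sel <- select_variant_set(snap, "select_clinvar")
  full <- select_variant_set(snap, "full_clinvar")
  expect_true(all(sel %in% full))
  # P 0-star is full-only; Conflicting excluded from both
  p0 <- snap$id[snap$tier == "P" & snap$stars == 0]
  conf <- snap$id[snap$tier == "Conflicting"]
  expect_true(all(!p0 %in% sel) && all(p0 %in% full))
  expect_true(all(!conf %in% full))
  expect_error(select_variant_set(snap, "galaxy_set"))

  hsnaps <- gen_snapshot_series(panel, dates = "2016-01-01",
    dialect = "hgmd", seed = 9, n_background = 40)
  htl <- build_timelines(hsnaps$files)
  hsnap <- snapshot_at(htl, "2016-01-01")
  hs <- select_variant_set(hsnap, "select_hgmd")
  hf <- select_variant_set(hsnap, "full_hgmd")
  expect_true(all(hs %in% hf))
  dmq <- hsnap$id[hsnap$category == "DM?"]
  expect_true(length(dmq) > 0 && all(dmq %in% hf) && all(!dmq %in% hs))
})

test_that("somatic-only and null-alt records never enter a timeline", {
  d <- withr::local_tempdir()
  vcf <- file.path(d, "s.vcf")
  writeLines(c("##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
      "INFO"), collapse = "\t"),
    "chr1\t100\t.\tA\tG\t.\t.\tCLNSIG=Pathogenic;CLNREVSTAT=criteria_provided,_single_submitter",
    "chr1\t200\t.\tA\t.\t.\t.\tCLNSIG=Pathogenic;CLNREVSTAT=criteria_provided,_single_submitter",
    "chr1\t300\t.\tA\tG\t.\t.\tCLNSIG=Pathogenic;CLNREVSTAT=criteria_provided,_single_submitter;CLNORIGIN=2"),
    vcf)
  snap <- read_snapshot_vcf(vcf, "archive2", "2016-01-01")
  expect_equal(snap$pos, 100L)
})

test_that("archive-1 stars are withheld before the cutover date", {
  d <- withr::local_tempdir()
  vcf <- file.path(d, "a1.vcf")
  writeLines(c("##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
      "INFO"), collapse = "\t"),
    "chr1\t100\t.\tA\tG\t.\t.\tCLNSIG=5;CLNREVSTAT=single"), vcf)
  pre <- read_snapshot_vcf(vcf, "archive1", "2015-01-01")
  expect_true(is.na(pre$stars))
  post <- read_snapshot_vcf(vcf, "archive1", "2015-07-01")
  expect_equal(post$stars, 1L)
  # star-dependent selection excludes the starless pre-cutover record
  pre$category <- NA_character_
  expect_equal(length(select_variant_set(pre, "select_clinvar")), 0L)
  expect_equal(length(select_variant_set(pre, "full_clinvar")), 1L)
})

test_that("harmonized timelines round-trip through TSV", {
  panel <- gen_panel(2, 1, seed = 4)
  snaps <- gen_snapshot_series(panel,
    dates = c("2016-01-01", "2016-06-01", "2017-01-01"),
    recat_spec = data.frame(from = "P/LP_1", to = "VUS",
      date = "2016-06-01"),
    dialect = "archive2", seed = 4)
  tl <- build_timelines(snaps$files)
  d <- withr::local_tempdir()
  path <- file.path(d, "timeline.tsv")
  utils::write.table(tl, path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  back <- utils::read.delim(path, stringsAsFactors = FALSE,
    check.names = FALSE)
  expect_equal(back$id, tl$id)
  expect_equal(back$date, tl$date)
  expect_equal(back$category, tl$category)
  expect_equal(back$stars, tl$stars)
})
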