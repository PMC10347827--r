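# Recategorization: monthly downsampling, event extraction (including
# removal / re-entry), first/last transitions, variant-months and
# ancestry-normalized rates.

# long timeline frame from a compact list: id -> (date -> category)
tl_frame <- function(spec, database = "clinvar") {
  do.call(rbind, lapply(names(spec), function(id) {
    ent <- spec[[id]]
    data.frame(id = id, database = database, date = names(ent),
      category = unname(ent), stringsAsFactors = FALSE)
  }))
}

test_that("monthly downsampling keeps the configured representative", {
  dates <- c("2019-03-01", "2019-03-08", "2019-03-15", "2019-03-29",
    "2019-05-10")
  expect_equal(downsample_monthly(dates),
    as.Date(c("2019-03-29", "2019-05-10")))
  expect_equal(downsample_monthly(dates, "first"),
    as.Date(c("2019-03-01", "2019-05-10")))
  monthly <- as.Date(c("2019-01-15", "2019-02-15"))
  expect_equal(downsample_monthly(monthly), monthly)
  expect_length(downsample_monthly(character(0)), 0)
})

test_that("adjacent category changes become events with ladder direction
           and confidence class", {
  tl <- tl_frame(list(
    const = c("2016-01-01" = "P/LP_1", "2016-02-01" = "P/LP_1"),
    star_up = c("2016-01-01" = "P/LP_1", "2016-02-01" = "P/LP_2"),
    to_conf = c("2016-01-01" = "P/LP_1", "2016-02-01" = "Conflicting"),
    from_vus = c("2016-01-01" = "VUS", "2016-02-01" = "B/LB_2")))
  ev <- extract_events(tl, "clinvar")
  expect_false("const" %in% ev$id)
  su <- ev[ev$id == "star_up", ]
  expect_equal(su$direction, "toward_pathogenic")
  expect_false(su$is_reclassification)
  expect_equal(su$confidence_change, "neither")
  tc <- ev[ev$id == "to_conf", ]
  expect_equal(tc$direction, "toward_benign")
  expect_true(tc$is_reclassification)
  expect_equal(tc$confidence_change, "decreasing")
  fv <- ev[ev$id == "from_vus", ]
  expect_equal(fv$confidence_change, "increasing")
  expect_equal(fv$direction, "toward_benign")
})

test_that("events before the review-star boundary are not counted for
           the ClinVar ladder", {
  tl <- tl_frame(list(
    early = c("2015-01-01" = "VUS", "2015-05-01" = "Conflicting"),
    late = c("2015-05-01" = "VUS", "2015-08-01" = "Conflicting")))
  ev <- extract_events(tl, "clinvar")
  expect_equal(ev$id, "late")
})

test_that("removal emits nothing; re-entry under a new category emits one
           event from the pre-removal category", {
  tl <- tl_frame(list(
    gone = c("2016-01-01" = "P/LP_1", "2016-02-01" = "P/LP_1"),
    back_same = c("2016-01-01" = "P/LP_1", "2016-03-01" = "P/LP_1"),
    back_new = c("2016-01-01" = "P/LP_1", "2016-03-01" = "VUS"),
    anchor = c("2016-01-01" = "VUS", "2016-02-01" = "VUS",
      "2016-03-01" = "VUS")))
  ev <- extract_events(tl, "clinvar")
  expect_false("gone" %in% ev$id)
  expect_false("back_same" %in% ev$id)
  bn <- ev[ev$id == "back_new", ]
  expect_equal(nrow(bn), 1L)
  expect_equal(bn$from, "P/LP_1")
  expect_equal(bn$to, "VUS")
  expect_true(bn$re_entered)
  expect_equal(bn$confidence_change, "decreasing")
})

test_that("HGMD DM to DM? is a reduced-pathogenicity recategorization", {
  tl <- tl_frame(list(v = c("2014-06-01" = "DM", "2016-06-01" = "DM?")),
    database = "hgmd")
  ev <- extract_events(tl, "hgmd")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$direction, "toward_benign")
})

test_that("first/last transitions collapse multi-hop paths", {
  tl <- tl_frame(list(
    single = c("2016-01-01" = "VUS"),
    hops = c("2016-01-01" = "P/LP_1", "2016-02-01" = "P/LP_2",
      "2016-03-01" = "Conflicting")))
  fl <- first_last_transition(tl)
  expect_equal(fl$first[fl$id == "single"], "VUS")
  expect_equal(fl$last[fl$id == "single"], "VUS")
  expect_equal(fl$first[fl$id == "hops"], "P/LP_1")
  expect_equal(fl$last[fl$id == "hops"], "Conflicting")
})

test_that("first/last underestimates or equals the full event count", {
  set.seed(404)
  cats <- clinvar_ladder()
  for (rep_i in 1:20) {
    months <- format(seq(as.Date("2016-01-01"), by = "month",
      length.out = 8), "%Y-%m-%d")
    spec <- lapply(1:6, function(i) {
      x <- sample(cats, 8, replace = TRUE)
      names(x) <- months
      x
    })
    names(spec) <- paste0("v", 1:6)
    tl <- tl_frame(spec)
    ev <- extract_events(tl, "clinvar")
    fl <- first_last_transition(tl)
    expect_gte(nrow(ev), sum(fl$first != fl$last))
  }
})

test_that("variant-months worked example and partition conservation", {
  # 2 variants for 1 month = 2 variant-months; 1 variant for 2 months = 2
  two_one <- tl_frame(list(
    a = c("2016-01-15" = "P/LP_1"), b = c("2016-01-15" = "P/LP_1")))
  one_two <- tl_frame(list(
    a = c("2016-01-15" = "P/LP_1", "2016-02-15" = "P/LP_1")))
  expect_equal(variant_months(two_one, "P/LP_1"), 2)
  expect_equal(variant_months(one_two, "P/LP_1"), 2)
  expect_equal(variant_months(one_two, character(0)), 0)

  set.seed(11)
  months <- format(seq(as.Date("2016-01-01"), by = "month",
    length.out = 12), "%Y-%m-%d")
  spec <- lapply(1:9, function(i) {
    keep <- sort(sample(12, sample(3:12, 1)))
    x <- sample(clinvar_ladder(), length(keep), replace = TRUE)
    names(x) <- months[keep]
    x
  })
  names(spec) <- paste0("v", 1:9)
  tl <- tl_frame(spec)
  total <- variant_months(tl, clinvar_ladder())
  parts <- list(grep("^P/LP", clinvar_ladder(), value = TRUE),
    grep("^B/LB", clinvar_ladder(), value = TRUE),
    c("VUS", "Conflicting"))
  expect_equal(sum(vapply(parts, function(p) variant_months(tl, p), 0)),
    total)
  expect_equal(total, nrow(tl[as.Date(tl$date) >=
    as.Date("2015-06-15"), ]))
})

test_that("reclassification rate follows the Wald formula and its
           scaling properties", {
  r0 <- reclass_rate(0, 1000)
  expect_equal(c(r0$rate, r0$ci_low, r0$ci_high), c(0, 0, 0))
  r <- reclass_rate(5, 1000)
  p <- 5 / 1000
  half <- 1.96 * sqrt(p * (1 - p) / 1000)
  expect_equal(r$rate, p)
  expect_equal(r$ci_low, p - half)
  expect_equal(r$ci_high, p + half)
  r2 <- reclass_rate(10, 2000)
  expect_equal(r2$rate, r$rate)
  expect_lt(r2$ci_high - r2$ci_low, r$ci_high - r$ci_low)
  expect_true(is.na(reclass_rate(0, 0)$rate))
  expect_equal(reclass_rate(1, 50)$ci_low, 0)  # clipped at zero
})

test_that("ancestry rate comparison flags a planted elevation and matches
           the pairwise hypergeometric oracle", {
  vm <- c(AFR = 900, AMR = 900, EAS = 900, EUR = 900, SAS = 900)
  ev <- c(AFR = 5, AMR = 5, EAS = 5, EUR = 40, SAS = 5)
  ledger <- new_test_ledger()
  res <- compare_ancestry_rates(ev, vm, ledger = ledger)
  expect_lt(res$omnibus$p_value, 1e-6)
  eur_up <- res$pairwise[res$pairwise$higher == "EUR", ]
  expect_true(all(eur_up$p < 2.2e-4))
  expect_equal(ledger$n, 1L + 20L)

  null_res <- compare_ancestry_rates(
    c(AFR = 5, AMR = 5, EAS = 5, EUR = 5, SAS = 5), vm)
  expect_gt(null_res$omnibus$p_value, 0.9)
  expect_null(null_res$pairwise)

  small <- matrix(c(3, 40, 1, 60), 2, byrow = TRUE)
  expect_equal(fisher_2x2(small, "greater"),
    oracle_fisher_2x2(small, "greater"), tolerance = 1e-10)
})

test_that("planted transitions in a generated series are recovered
           exactly, per dialect", {
  panel <- gen_panel(4, 1, seed = 21)
  dates <- format(seq(as.Date("2015-07-01"), by = "month",
    length.out = 24), "%Y-%m-%d")
  spec <- data.frame(
    from = c("P/LP_1", "VUS", "B/LB_1"),
    to = c("Conflicting", "P/LP_2", "VUS"),
    date = c("2016-03-01", "2016-09-01", "2017-02-01"),
    via_removal = c(FALSE, FALSE, TRUE))
  snaps <- gen_snapshot_series(panel, dates, spec, dialect = "archive2",
    seed = 22)
  tl <- build_timelines(snaps$files)
  ev <- extract_events(tl, "clinvar")
  pl <- snaps$ledger$planted_recats
  expect_equal(nrow(ev), nrow(pl))
  key <- function(d) sort(paste(d$id, d$from, d$to))
  expect_equal(key(ev), key(pl))
  expect_equal(sum(ev$re_entered), 1L)

  hspec <- data.frame(from = "DM", to = "DM?", date = "2016-03-01")
  hsnaps <- gen_snapshot_series(panel, dates[c(1, 6, 12, 20)], hspec,
    dialect = "hgmd", seed = 23)
  hev <- extract_events(build_timelines(hsnaps$files), "hgmd")
  expect_equal(nrow(hev), 1L)
  expect_equal(hev$id, hsnaps$ledger$planted_recats$id)
  expect_equal(hev$direction, "toward_benign")
})

test_that("star-level collapse yields the cross-database ladder", {
  expect_equal(collapse_star_levels(c("P/LP_2", "B/LB_0", "VUS",
    "Conflicting")), c("P/LP", "B/LB", "VUS", "Conflicting"))
})
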