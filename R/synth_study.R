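# One-call synthetic study bundle: panel + phased cohort + classification
# snapshot series (ClinVar dialects and HGMD) + frequency tables, all
# coordinated so cohort-planted pathogenic variants appear in the snapshot
# series, with a merged machine-readable ground-truth ledger.

#' Default cohort composition: the five-continental-ancestry reference
#' cohort (2504 samples: 661 AFR, 347 AMR, 504 EAS, 503 EUR, 489 SAS)
#' @return Named integer vector.
#' @export
default_ancestry_sizes <- function() {
  c(AFR = 661L, AMR = 347L, EAS = 504L, EUR = 503L, SAS = 489L)
}

#' Default planted-affected specification
#'
#' Mirrors the ancestry composition observed for the Select-HGMD 2014
#' audit: 37 indicated-affected individuals, 25 of African ancestry and
#' none of European ancestry, across all three mechanisms.
#'
#' @return data.frame (mechanism, ancestry).
#' @export
default_affected_spec <- function() {
  data.frame(
    mechanism = c(rep("hom", 17), rep("comphet", 6), rep("hemi", 2),
      rep("hom", 3), "comphet",
      rep("hom", 3), "comphet",
      rep("hom", 2), "comphet", "hemi"),
    ancestry = c(rep("AFR", 25), rep("AMR", 4), rep("EAS", 4),
      rep("SAS", 4)),
    stringsAsFactors = FALSE)
}

#' Default planted recategorization timeline (ClinVar dialect)
#' @return data.frame (from, to, date, via_removal).
#' @export
default_recat_spec <- function() {
  data.frame(
    from = c("P/LP_1", "P/LP_1", "VUS", "B/LB_1", "P/LP_1", "VUS"),
    to = c("P/LP_2", "Conflicting", "P/LP_1", "VUS", "VUS",
      "Conflicting"),
    date = c("2017-03-01", "2018-06-01", "2019-01-01", "2017-09-01",
      "2019-06-01", "2016-03-01"),
    via_removal = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

#' Generate a coordinated synthetic study bundle
#'
#' Composes [gen_panel()], [gen_cohort()], [gen_snapshot_series()] (a
#' ClinVar-dialect series spanning the archive-1/archive-2 cutover and an
#' HGMD-dialect series at three archive dates) and [gen_frequency_table()],
#' writes every artifact under `dir`, and merges the per-generator ground
#' truth into one ledger (written as `ledger.json`). Cohort-planted
#' pathogenic variants are carried in the ClinVar series as Pathogenic with
#' 1 review star and in the HGMD series as DM, so they are members of both
#' the Select and Full variant sets.
#'
#' @param dir Output directory.
#' @param seed Integer master seed; per-artifact seeds are derived from it
#'   and recorded in the ledger.
#' @param ancestry_sizes,affected_spec,recat_spec,common_spec,global_spec
#'   Study conditions; defaults are the package's reference conditions
#'   (see the individual generators).
#' @param hgmd_recat_spec Planted HGMD transitions (default one DM -> DM?).
#' @param dates ClinVar snapshot dates (default: first of each month,
#'   2014-04 through 2020-12).
#' @param hgmd_dates HGMD snapshot dates (default three archive dates).
#' @param n_background_snapshot Constant-category background variants in
#'   each snapshot series.
#' @return list with file paths, in-memory objects and the merged `ledger`.
#' @export
gen_study <- function(dir = tempfile("study"), seed = 1L,
                      ancestry_sizes = default_ancestry_sizes(),
                      affected_spec = default_affected_spec(),
                      recat_spec = default_recat_spec(),
                      hgmd_recat_spec = data.frame(
                        from = c("DM", "DM?"), to = c("DM?", "DM"),
                        date = c("2016-06-01", "2020-09-01"),
                        stringsAsFactors = FALSE),
                      common_spec = NULL, global_spec = NULL,
                      dates = seq(as.Date("2014-04-01"),
                        as.Date("2020-12-01"), by = "month"),
                      hgmd_dates = as.Date(c("2014-04-01", "2016-06-01",
                        "2020-09-01")),
                      n_background_snapshot = 20L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  seeds <- list(panel = seed, cohort = seed + 1000L,
    clinvar = seed + 2000L, hgmd = seed + 3000L, frequency = seed + 4000L)

  panel <- gen_panel(8L, 2L, seed = seeds$panel)
  write_panel(panel, file.path(dir, "panel.tsv"))

  cohort <- gen_cohort(panel, ancestry_sizes, affected_spec,
    seed = seeds$cohort)
  write_cohort(cohort, file.path(dir, "cohort.vcf"),
    file.path(dir, "samples.tsv"))

  carried <- data.frame(id = cohort$variants$id,
    category = "P/LP_1", tier = "P", stringsAsFactors = FALSE)
  carried <- cbind(parse_key(carried$id)[, c("chrom", "pos", "ref", "alt")],
    carried)

  clinvar <- gen_snapshot_series(panel, dates, recat_spec,
    dialect = "clinvar_auto", seed = seeds$clinvar,
    dir = file.path(dir, "clinvar"), extra_variants = carried,
    n_background = n_background_snapshot)

  carried_hgmd <- carried
  carried_hgmd$category <- "DM"
  hgmd <- gen_snapshot_series(panel, hgmd_dates, hgmd_recat_spec,
    dialect = "hgmd", seed = seeds$hgmd,
    dir = file.path(dir, "hgmd"), extra_variants = carried_hgmd,
    n_background = n_background_snapshot)

  # default BA1 plants: one AFR-common variant tripping both rules via the
  # weighted mean, one AFR-elevated variant tripping only the 2018
  # population rule, one common in the 1KGP-role dataset
  snap_ids <- setdiff(clinvar$variants$id, cohort$variants$id)
  if (is.null(common_spec) && length(snap_ids) >= 2L) {
    common_spec <- data.frame(id = snap_ids[1:2], ancestry = "AFR",
      maf = c(0.20, 0.08), stringsAsFactors = FALSE)
  }
  if (is.null(global_spec) && length(snap_ids) >= 3L) {
    global_spec <- data.frame(id = snap_ids[3], dataset = "kgp",
      maf = 0.12, stringsAsFactors = FALSE)
  }
  freq <- gen_frequency_table(cohort, seed = seeds$frequency,
    common_spec = common_spec, global_spec = global_spec,
    extra_ids = clinvar$variants$id)
  write_frequency_table(freq$records, file.path(dir, "frequency.tsv"))

  ledger <- list(
    planted_affected = cohort$ledger$planted_affected,
    planted_recats = clinvar$ledger$planted_recats,
    planted_recats_hgmd = hgmd$ledger$planted_recats,
    planted_ba1 = freq$ledger$planted_ba1,
    seeds = seeds)
  jsonlite::write_json(ledger, file.path(dir, "ledger.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)

  list(dir = dir, panel = panel, cohort = cohort, clinvar = clinvar,
    hgmd = hgmd, freq = freq, ledger = ledger,
    paths = list(panel = file.path(dir, "panel.tsv"),
      cohort_vcf = file.path(dir, "cohort.vcf"),
      sample_sheet = file.path(dir, "samples.tsv"),
      frequency = file.path(dir, "frequency.tsv"),
      ledger = file.path(dir, "ledger.json")))
}
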