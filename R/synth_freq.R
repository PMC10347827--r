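# Synthetic population-stratified allele-frequency tables. Emits a long
# TSV-able table (id, dataset, population, maf, n) with per-population rows
# for the continental-population dataset plus a global "ALL" row per
# dataset whose MAF is the sample-size-weighted mean of its populations.

# gnomAD v2.1 exome continental sample sizes, the defaults a user would
# swap for their own frequency resource
default_population_sizes <- function() {
  c(AFR = 8128, AMR = 17296, EAS = 9197, EUR = 56885, SAS = 15308)
}

#' Generate a population-stratified frequency table for cohort variants
#'
#' Every cohort variant receives a per-population MAF in the
#' continental-population dataset (`gnomad` role): a small background value
#' drawn around the MAF floor unless overridden by `common_spec`, which
#' plants (variant, ancestry, MAF) values — e.g. common ancestry-specific
#' variants that should trip the BA1 filters. Global rows (population
#' "ALL") are the sample-size-weighted means. Two global-only datasets
#' (`kgp`, `esp` roles) are emitted for the 2015 BA1 rule; their globals
#' default to rare values and can be overridden via `global_spec`.
#'
#' @param cohort Cohort from [gen_cohort()] (or any list with a
#'   `variants$id` vector); extra variant ids may be supplied via
#'   `extra_ids`.
#' @param populations Named vector ancestry -> sample count for the
#'   continental dataset (default [default_population_sizes()]).
#' @param common_spec data.frame (id, ancestry, maf) of planted
#'   population MAFs; `maf` in [0, 1] (values above 0.5 only make sense
#'   when exercising BA1).
#' @param seed Integer seed.
#' @param global_spec data.frame (id, dataset, maf) of planted global MAFs
#'   for the `kgp`/`esp` datasets.
#' @param extra_ids Additional variant ids to cover.
#' @param zero_ids Variant ids forced to zero MAF in all ancestries (not
#'   assignable to any ancestry downstream).
#' @return list with `records` (long data.frame id, dataset, population,
#'   maf, n) and `ledger` (planted_ba1: id, rule in 2015/2018/both; seed).
#' @export
gen_frequency_table <- function(cohort, populations = NULL,
                                common_spec = NULL, seed = 1L,
                                global_spec = NULL, extra_ids = NULL,
                                zero_ids = NULL) {
  populations <- populations %||% default_population_sizes()
  stopifnot(!is.null(names(populations)), all(populations > 0))
  ids <- unique(c(cohort$variants$id, extra_ids))
  if (!is.null(common_spec) && nrow(common_spec) > 0L) {
    bad <- setdiff(common_spec$ancestry, names(populations))
    if (length(bad) > 0L) stop("unknown ancestry label(s): ",
      paste(bad, collapse = ", "))
    stopifnot(all(common_spec$maf >= 0), all(common_spec$maf <= 1),
      all(common_spec$id %in% ids))
  }
  pops <- names(populations)
  floor_ <- 1 / (2 * min(populations))

  with_seed(seed, {
    maf <- matrix(0, nrow = length(ids), ncol = length(pops),
      dimnames = list(ids, pops))
    # background: mostly sub-floor noise, some clearly above
    hi <- max(1e-3, floor_ * 4)
    for (p in pops) {
      maf[, p] <- ifelse(stats::runif(length(ids)) < 0.5,
        stats::runif(length(ids), 0, floor_ * 0.9),
        stats::runif(length(ids), floor_ * 2, hi))
    }
    if (!is.null(zero_ids)) maf[intersect(zero_ids, ids), ] <- 0
    if (!is.null(common_spec)) {
      for (i in seq_len(NROW(common_spec))) {
        maf[common_spec$id[i], common_spec$ancestry[i]] <- common_spec$maf[i]
      }
    }
    w <- populations / sum(populations)
    global_gnomad <- as.numeric(maf %*% w)

    g_kgp <- stats::runif(length(ids), 0, 1e-3)
    g_esp <- stats::runif(length(ids), 0, 1e-3)
    names(g_kgp) <- names(g_esp) <- ids
    if (!is.null(global_spec)) {
      for (i in seq_len(NROW(global_spec))) {
        if (global_spec$dataset[i] == "kgp") {
          g_kgp[global_spec$id[i]] <- global_spec$maf[i]
        } else if (global_spec$dataset[i] == "esp") {
          g_esp[global_spec$id[i]] <- global_spec$maf[i]
        } else stop("global_spec dataset must be 'kgp' or 'esp'")
      }
    }

    records <- rbind(
      do.call(rbind, lapply(pops, function(p) {
        data.frame(id = ids, dataset = "gnomad", population = p,
          maf = maf[, p], n = unname(populations[p]),
          stringsAsFactors = FALSE)
      })),
      data.frame(id = ids, dataset = "gnomad", population = "ALL",
        maf = global_gnomad, n = sum(populations), stringsAsFactors = FALSE),
      data.frame(id = ids, dataset = "kgp", population = "ALL",
        maf = unname(g_kgp), n = 2504, stringsAsFactors = FALSE),
      data.frame(id = ids, dataset = "esp", population = "ALL",
        maf = unname(g_esp), n = 6500, stringsAsFactors = FALSE))
    rownames(records) <- NULL

    # ground truth for the BA1 rules, derived arithmetically from the
    # emitted table (independently of the filter implementation)
    r2015 <- ids[global_gnomad > 0.05 | g_kgp[ids] > 0.05 |
      g_esp[ids] > 0.05]
    r2018 <- ids[g_kgp[ids] > 0.05 | g_esp[ids] > 0.05 |
      apply(maf > 0.05, 1L, any)]
    all_removed <- union(r2015, r2018)
    planted_ba1 <- data.frame(id = all_removed,
      rule = ifelse(all_removed %in% r2015 & all_removed %in% r2018,
        "both", ifelse(all_removed %in% r2015, "2015", "2018")),
      stringsAsFactors = FALSE)

    list(records = records,
      ledger = list(planted_ba1 = planted_ba1,
        seeds = list(frequency = seed)))
  })
}

#' Write / read a long frequency table TSV
#'
#' Columns: id, dataset, population ("ALL" for a dataset-global row),
#' maf, n (sample count behind the row).
#'
#' @param records Frequency records data.frame.
#' @param path TSV path.
#' @export
write_frequency_table <- function(records, path) write_tsv(records, path)

#' @rdname write_frequency_table
#' @export
read_frequency_table <- function(path) {
  rec <- read_tsv(path)
  stopifnot(all(c("id", "dataset", "population", "maf", "n") %in%
    names(rec)))
  rec
}
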