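# Allele-frequency handling: the MAF floor that equalizes resolution
# across unequally sized populations, the 2015 and 2018 BA1
# stand-alone-benign filters, and principal-ancestry assignment.

#' Smallest-possible-MAF floor for a set of population sample sizes
#'
#' One allele in the smallest population: `1 / (2 * min(N))`. With the
#' gnomAD v2.1 exome continental sizes (smallest: 8128 African-ancestry
#' individuals) this is 6.152e-5.
#'
#' @param population_N Named vector of diploid sample counts (all > 0).
#' @return The floor as a fraction.
#' @export
compute_maf_floor <- function(population_N) {
  if (length(population_N) == 0L) stop("empty population size map")
  stopifnot(all(population_N > 0))
  1 / (2 * min(population_N))
}

#' Zero out sub-floor population MAFs
#'
#' Population MAFs strictly below `floor` become 0; dataset-global rows
#' (population "ALL") are untouched. Idempotent.
#'
#' @param records Long frequency data.frame (id, dataset, population, maf,
#'   n).
#' @param floor Non-negative fraction.
#' @return The records with floored population MAFs.
#' @export
floor_mafs <- function(records, floor) {
  stopifnot(floor >= 0)
  pop <- records$population != "ALL"
  records$maf[pop & records$maf < floor] <- 0
  records
}

#' Assign each variant its principal ancestry
#'
#' The ancestry with the highest (floored) population MAF in the
#' continental-population dataset; variants with zero MAF in all
#' ancestries get "none" and are not considered further downstream. Exact
#' ties resolve to the lexicographically first ancestry label (logged).
#'
#' @param records Floored frequency records.
#' @param dataset Continental-population dataset name (default "gnomad").
#' @return data.frame (id, ancestry).
#' @export
assign_ancestry <- function(records, dataset = "gnomad") {
  r <- records[records$dataset == dataset & records$population != "ALL", ,
    drop = FALSE]
  r <- r[order(r$id, r$population), , drop = FALSE]
  out <- do.call(rbind, lapply(split(r, r$id), function(d) {
    if (all(d$maf == 0)) {
      anc <- "none"
    } else {
      best <- which(d$maf == max(d$maf))
      if (length(best) > 1L) {
        audit_msg("ancestry tie for ", d$id[1L], ": taking ",
          d$population[best[1L]])
      }
      anc <- d$population[best[1L]]   # rows sorted: lexicographic tie-break
    }
    data.frame(id = d$id[1L], ancestry = anc, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# global MAF per dataset for a set of ids; missing rows treated as 0
.global_maf <- function(records, ids, dataset) {
  r <- records[records$dataset == dataset & records$population == "ALL", ]
  g <- r$maf[match(ids, r$id)]
  miss <- is.na(g)
  if (any(miss)) {
    audit_msg("BA1: no global MAF for ", sum(miss), " variants in ",
      dataset, "; treating as 0")
    g[miss] <- 0
  }
  g
}

#' Apply the 2015 BA1 stand-alone-benign frequency filter
#'
#' A variant is removed iff its global MAF is strictly above 5% in any of
#' the configured reference datasets.
#'
#' @param variants Character vector of variant ids under consideration.
#' @param records Frequency records.
#' @param datasets Dataset names whose globals are checked (roles: the
#'   population-reference, exome-panel and aggregation datasets).
#' @param threshold Frequency cutoff, default 0.05 (strict >).
#' @return list(kept = ids, removed = data.frame(id, rule_year, maf,
#'   dataset, population)).
#' @export
apply_ba1_2015 <- function(variants, records,
                           datasets = c("kgp", "esp", "gnomad"),
                           threshold = 0.05) {
  removed <- NULL
  for (ds in datasets) {
    g <- .global_maf(records, variants, ds)
    hit <- g > threshold
    if (any(hit)) {
      removed <- rbind(removed, data.frame(id = variants[hit],
        rule_year = 2015L, maf = g[hit], dataset = ds,
        population = "ALL", stringsAsFactors = FALSE))
    }
  }
  if (is.null(removed)) {
    removed <- data.frame(id = character(0), rule_year = integer(0),
      maf = numeric(0), dataset = character(0), population = character(0),
      stringsAsFactors = FALSE)
  }
  list(kept = setdiff(variants, removed$id), removed = removed)
}

#' Apply the 2018 BA1 stand-alone-benign frequency filter
#'
#' A variant is removed iff its global MAF is strictly above 5% in the
#' population-reference or exome-panel dataset, or its MAF is strictly
#' above 5% in any continental population of the aggregation dataset with
#' at least `min_alleles` alleles.
#'
#' @inheritParams apply_ba1_2015
#' @param global_datasets Datasets checked on their global MAF.
#' @param population_dataset Dataset checked per continental population.
#' @param min_alleles Minimum allele count (2N) for a population to
#'   qualify, default 2000.
#' @return list(kept, removed) as in [apply_ba1_2015()].
#' @export
apply_ba1_2018 <- function(variants, records,
                           global_datasets = c("kgp", "esp"),
                           population_dataset = "gnomad",
                           threshold = 0.05, min_alleles = 2000) {
  removed <- NULL
  for (ds in global_datasets) {
    g <- .global_maf(records, variants, ds)
    hit <- g > threshold
    if (any(hit)) {
      removed <- rbind(removed, data.frame(id = variants[hit],
        rule_year = 2018L, maf = g[hit], dataset = ds,
        population = "ALL", stringsAsFactors = FALSE))
    }
  }
  p <- records[records$dataset == population_dataset &
    records$population != "ALL" & records$id %in% variants &
    2 * records$n >= min_alleles, , drop = FALSE]
  hit <- p$maf > threshold
  if (any(hit)) {
    removed <- rbind(removed, data.frame(id = p$id[hit],
      rule_year = 2018L, maf = p$maf[hit], dataset = population_dataset,
      population = p$population[hit], stringsAsFactors = FALSE))
  }
  if (is.null(removed)) {
    removed <- data.frame(id = character(0), rule_year = integer(0),
      maf = numeric(0), dataset = character(0), population = character(0),
      stringsAsFactors = FALSE)
  }
  list(kept = setdiff(variants, removed$id), removed = removed)
}
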