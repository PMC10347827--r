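# Cohort burden scan: database-implied pathogenic genotypes (homozygous,
# hemizygous, compound heterozygous), yearly maxima and false-positive
# rates.

# parse a phased GT matrix (variants x samples) into two haplotype 0/1
# matrices; returns NULL columns handling via the `unphased` policy
.split_haplotypes <- function(gt, unphased = c("skip", "error")) {
  unphased <- match.arg(unphased)
  phased <- grepl("|", gt, fixed = TRUE)
  miss <- is.na(gt) | gt %in% c(".", "./.", ".|.")
  bad <- !phased & !miss
  if (any(bad)) {
    if (unphased == "error") stop("unphased genotype encountered")
    warning(sum(bad), " unphased genotype(s) skipped", call. = FALSE)
  }
  a1 <- matrix(0L, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  a2 <- a1
  ok <- phased & !miss
  alleles <- strsplit(gt[ok], "|", fixed = TRUE)
  a1[ok] <- as.integer(vapply(alleles, `[`, "", 1L) != "0")
  a2[ok] <- as.integer(vapply(alleles, `[`, "", 2L) != "0")
  list(h1 = a1, h2 = a2)
}

#' Detect indicated-affected individuals for one variant set
#'
#' Scans phased cohort genotypes, restricted to `variant_set`, for
#' database-implied pathogenic genotypes: homozygous alt at one variant,
#' hemizygous (male, any alt allele in an X-linked panel gene), or
#' compound heterozygous (two distinct variants in the same gene on
#' opposite haplotypes). Females homozygous in an X-linked gene count as
#' hom. One call is emitted per (sample, gene), labelled with the most
#' specific mechanism (hemi over hom over comphet); a sample may be called
#' in several genes but is counted once in individual totals.
#'
#' @param cohort Cohort list (variants, gt, samples).
#' @param variant_set Character vector of variant ids in the set.
#' @param panel Gene panel data.frame.
#' @param unphased "skip" (default: skip with a warning) or "error".
#' @return data.frame (sample, gene, mechanism, variants, ancestry).
#' @export
detect_affected <- function(cohort, variant_set, panel,
                            unphased = c("skip", "error")) {
  unphased <- match.arg(unphased)
  empty <- data.frame(sample = character(0), gene = character(0),
    mechanism = character(0), variants = character(0),
    ancestry = character(0), stringsAsFactors = FALSE)
  keep <- cohort$variants$id %in% variant_set
  if (!any(keep)) return(empty)
  v <- assign_gene(cohort$variants[keep, , drop = FALSE], panel)
  in_gene <- !is.na(v$gene)
  if (!any(in_gene)) return(empty)
  v <- v[in_gene, , drop = FALSE]
  gt <- cohort$gt[v$id, , drop = FALSE]
  haps <- .split_haplotypes(gt, unphased)
  h1 <- haps$h1; h2 <- haps$h2
  male <- cohort$samples$sex[match(colnames(gt),
    cohort$samples$sample)] == "male"
  anc <- cohort$samples$ancestry[match(colnames(gt),
    cohort$samples$sample)]

  calls <- list()
  for (g in unique(v$gene)) {
    gi <- which(v$gene == g)
    xl <- v$inheritance[gi[1L]] == "XL"
    g1 <- h1[gi, , drop = FALSE]
    g2 <- h2[gi, , drop = FALSE]
    hom_at <- g1 == 1L & g2 == 1L
    is_hom <- colSums(hom_at) > 0L
    any_alt <- colSums(g1 + g2) > 0L
    is_hemi <- xl & male & any_alt
    n1 <- colSums(g1); n2 <- colSums(g2)
    shared <- colSums(g1 & g2)
    is_ch <- n1 > 0L & n2 > 0L & !(n1 == 1L & n2 == 1L & shared == 1L)
    for (s in which(is_hemi)) {
      vid <- v$id[gi[which(g1[, s] + g2[, s] > 0L)[1L]]]
      calls[[length(calls) + 1L]] <- data.frame(
        sample = colnames(gt)[s], gene = g, mechanism = "hemi",
        variants = vid, ancestry = anc[s], stringsAsFactors = FALSE)
    }
    for (s in which(is_hom & !is_hemi)) {
      vid <- v$id[gi[which(hom_at[, s])[1L]]]
      calls[[length(calls) + 1L]] <- data.frame(
        sample = colnames(gt)[s], gene = g, mechanism = "hom",
        variants = vid, ancestry = anc[s], stringsAsFactors = FALSE)
    }
    for (s in which(is_ch & !is_hemi & !is_hom)) {
      i1 <- which(g1[, s] == 1L)
      i2 <- which(g2[, s] == 1L)
      pair <- NULL
      for (i in i1) {
        j <- i2[i2 != i]
        if (length(j) > 0L) { pair <- c(i, j[1L]); break }
      }
      if (is.null(pair)) next
      calls[[length(calls) + 1L]] <- data.frame(
        sample = colnames(gt)[s], gene = g, mechanism = "comphet",
        variants = paste(v$id[gi[sort(pair)]], collapse = ","),
        ancestry = anc[s], stringsAsFactors = FALSE)
    }
  }
  if (length(calls) == 0L) return(empty)
  out <- do.call(rbind, calls)
  out[order(out$sample, out$gene), , drop = FALSE]
}

#' Yearly maximum of distinct indicated-affected individuals
#'
#' For each calendar year with at least one snapshot, the maximum number
#' of distinct affected individuals over that year's snapshots.
#'
#' @param calls data.frame with columns sample, date (and optionally
#'   set_name; the maximum is taken within each set).
#' @return data.frame (set_name if present, year, n_affected).
#' @export
yearly_max <- function(calls) {
  if (nrow(calls) == 0L) {
    return(data.frame(year = integer(0), n_affected = integer(0)))
  }
  grp <- if ("set_name" %in% names(calls)) calls$set_name else ""
  per_date <- stats::aggregate(sample ~ grp + date, data = data.frame(
    grp = grp, date = calls$date, sample = calls$sample),
    FUN = function(x) length(unique(x)))
  per_date$year <- as.integer(format(as.Date(per_date$date), "%Y"))
  out <- stats::aggregate(sample ~ grp + year, data = per_date, FUN = max)
  names(out)[names(out) == "sample"] <- "n_affected"
  names(out)[names(out) == "grp"] <- "set_name"
  if (!"set_name" %in% names(calls)) out$set_name <- NULL
  out[order(out$year), , drop = FALSE]
}

#' False-positive rate per 1000 cataloged variants
#'
#' Indicated-affected individuals divided by the number of cataloged
#' variants in the set, per 1000. Undefined (NA) when the set is empty.
#'
#' @param n_affected Affected-individual count.
#' @param n_variants Variant count in the set.
#' @return Rate per 1000 variants (NA if `n_variants` is 0).
#' @export
fp_rate <- function(n_affected, n_variants) {
  ifelse(n_variants > 0, 1000 * n_affected / n_variants, NA_real_)
}

#' Expected number of truly affected individuals in the cohort
#'
#' @param cohort_size Number of individuals.
#' @param incidence Disease incidence as a fraction in (0, 1).
#' @return `cohort_size * incidence`.
#' @export
expected_affected <- function(cohort_size, incidence) {
  stopifnot(incidence > 0, incidence < 1, cohort_size >= 0)
  cohort_size * incidence
}

#' Run the burden scan across snapshot dates and variant sets
#'
#' @param cohort Cohort list.
#' @param timelines Long timeline data.frame from [build_timelines()].
#' @param panel Gene panel.
#' @param sets Variant-set names to audit.
#' @param ba1 Optional function(ids, date) -> kept ids, applied to each
#'   set before detection (both variants of a compound heterozygote must
#'   individually survive the filter).
#' @param unphased Passed to [detect_affected()].
#' @return list(calls = per-date call table with set_name/date/n_variants,
#'   summary = yearly BurdenSummary with fp_rate and per-ancestry counts).
#' @export
audit_burden <- function(cohort, timelines, panel,
                         sets = c("select_clinvar", "full_clinvar",
                           "select_hgmd", "full_hgmd"),
                         ba1 = NULL, unphased = "skip") {
  all_calls <- list()
  set_sizes <- list()
  for (db in unique(timelines$database)) {
    tl <- timelines[timelines$database == db, , drop = FALSE]
    db_sets <- sets[grepl(if (db == "hgmd") "hgmd" else "clinvar", sets)]
    for (d in sort(unique(tl$date))) {
      snap <- snapshot_at(tl, d)
      for (sn in db_sets) {
        ids <- select_variant_set(snap, sn)
        if (!is.null(ba1)) ids <- ba1(ids, d)
        set_sizes[[length(set_sizes) + 1L]] <- data.frame(
          set_name = sn, date = d, n_variants = length(ids),
          stringsAsFactors = FALSE)
        calls <- detect_affected(cohort, ids, panel, unphased = unphased)
        if (nrow(calls) > 0L) {
          calls$set_name <- sn
          calls$date <- d
          all_calls[[length(all_calls) + 1L]] <- calls
        }
      }
    }
  }
  calls <- if (length(all_calls) > 0L) do.call(rbind, all_calls) else
    data.frame(sample = character(0), gene = character(0),
      mechanism = character(0), variants = character(0),
      ancestry = character(0), set_name = character(0),
      date = character(0), stringsAsFactors = FALSE)
  sizes <- do.call(rbind, set_sizes)

  # yearly summary: max distinct individuals; variant count and ancestry
  # composition taken at the earliest snapshot achieving the maximum
  summaries <- list()
  for (sn in unique(sizes$set_name)) {
    sz <- sizes[sizes$set_name == sn, , drop = FALSE]
    years <- sort(unique(as.integer(format(as.Date(sz$date), "%Y"))))
    for (y in years) {
      dates_y <- sz$date[as.integer(format(as.Date(sz$date), "%Y")) == y]
      counts <- vapply(dates_y, function(d) {
        length(unique(calls$sample[calls$set_name == sn &
          calls$date == d]))
      }, 0L)
      best <- dates_y[which.max(counts)]
      n_aff <- max(counts)
      nv <- sz$n_variants[sz$date == best]
      anc_counts <- table(factor(
        unique(calls[calls$set_name == sn & calls$date == best,
          c("sample", "ancestry")])$ancestry,
        levels = sort(unique(cohort$samples$ancestry))))
      row <- data.frame(set_name = sn, year = y, n_affected = n_aff,
        n_variants = nv, fp_rate = fp_rate(n_aff, nv), date = best,
        stringsAsFactors = FALSE)
      for (a in names(anc_counts)) row[[paste0("n_", a)]] <-
        as.integer(anc_counts[[a]])
      summaries[[length(summaries) + 1L]] <- row
    }
  }
  summary <- do.call(rbind, summaries)
  list(calls = calls, summary = summary, set_sizes = sizes)
}
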