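# Recategorization analysis: monthly downsampling of snapshot series,
# event extraction (including removal / re-entry handling), first-vs-last
# transitions, variant-months exposure and ancestry-normalized
# reclassification rates.

#' Downsample snapshot dates to one representative per calendar month
#'
#' @param dates Vector of snapshot dates.
#' @param rule Which snapshot represents the month: "last" (default),
#'   "first", or "nearest_end" (closest to month end).
#' @return Sorted Date vector, one per month present in the input.
#' @export
downsample_monthly <- function(dates, rule = c("last", "first",
                                               "nearest_end")) {
  rule <- match.arg(rule)
  dates <- sort(unique(as.Date(dates)))
  if (length(dates) == 0L) return(dates)
  mo <- month_token(dates)
  picks <- vapply(split(dates, mo), function(d) {
    as.character(switch(rule,
      last = max(d),
      first = min(d),
      nearest_end = {
        eom <- seq(month_floor(d[1L]), by = "month", length.out = 2L)[2L] - 1
        d[which.min(abs(as.numeric(d - eom)))]
      }))
  }, "")
  sort(as.Date(unname(picks)))
}

# restrict a timeline frame to the monthly grid; NA-category rows (ladder
# levels the audit does not consider) are dropped, contributing neither
# variant-months nor events
monthly_timeline <- function(timelines, rule = "last") {
  tl <- timelines[!is.na(timelines$category), , drop = FALSE]
  grid <- downsample_monthly(unique(tl$date), rule = rule)
  tl <- tl[as.Date(tl$date) %in% grid, , drop = FALSE]
  tl$month <- month_token(tl$date)
  tl[order(tl$id, as.Date(tl$date)), , drop = FALSE]
}

#' Extract recategorization events from classification timelines
#'
#' One event per adjacent category change on the monthly grid. The removal
#' of a variant emits nothing; re-entry under a different category emits
#' one event from the pre-removal category (flagged `re_entered`); a
#' variant's first placement on the ladder is not an event. For the
#' ClinVar ladder, only events dated on or after `start_date` (the
#' review-star reliability boundary) are counted.
#'
#' Each event carries its direction on the ladder (toward_pathogenic /
#' toward_benign, by ladder-index sign), its confidence change (increasing
#' iff VUS/Conflicting to P/LP or B/LB; decreasing iff the reverse;
#' neither otherwise) and whether it is a reclassification (major-tier
#' change: P/LP vs VUS/Conflicting vs B/LB; every HGMD category is its own
#' major group).
#'
#' @param timelines Long timeline data.frame (id, database, date,
#'   category).
#' @param database "clinvar" or "hgmd" (ladder choice).
#' @param start_date Earliest countable ClinVar event date.
#' @param monthly_rule Passed to [downsample_monthly()].
#' @return data.frame (id, date, month, from, to, direction,
#'   confidence_change, is_reclassification, re_entered).
#' @export
extract_events <- function(timelines, database = c("clinvar", "hgmd"),
                           start_date = "2015-06-15",
                           monthly_rule = "last") {
  database <- match.arg(database)
  tl <- timelines[timelines$database == database, , drop = FALSE]
  tl <- monthly_timeline(tl, rule = monthly_rule)
  empty <- data.frame(id = character(0), date = character(0),
    month = character(0), from = character(0), to = character(0),
    direction = character(0), confidence_change = character(0),
    is_reclassification = logical(0), re_entered = logical(0),
    stringsAsFactors = FALSE)
  if (nrow(tl) == 0L) return(empty)
  grid <- sort(unique(as.Date(tl$date)))
  events <- list()
  for (d in split(tl, tl$id)) {
    if (nrow(d) < 2L) next
    dts <- as.Date(d$date)
    for (k in 2L:nrow(d)) {
      from <- d$category[k - 1L]
      to <- d$category[k]
      # snapshots between the two presence points with the variant absent
      gap <- any(grid > dts[k - 1L] & grid < dts[k])
      if (from == to) next
      if (database == "clinvar" && dts[k] < as.Date(start_date)) next
      i_from <- ladder_index(from, database)
      i_to <- ladder_index(to, database)
      conf <- confidence_change(from, to, database)
      events[[length(events) + 1L]] <- data.frame(
        id = d$id[1L], date = d$date[k], month = d$month[k],
        from = from, to = to,
        direction = if (i_to > i_from) "toward_pathogenic" else
          "toward_benign",
        confidence_change = conf,
        is_reclassification = !identical(major_tier(from, database),
          major_tier(to, database)),
        re_entered = gap, stringsAsFactors = FALSE)
    }
  }
  if (length(events) == 0L) return(empty)
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

confidence_change <- function(from, to, database = "clinvar") {
  if (database == "hgmd") return(rep("neither", length(from)))
  uncertain <- function(x) x %in% c("VUS", "Conflicting")
  classified <- function(x) grepl("^(P/LP|B/LB)", x)
  ifelse(uncertain(from) & classified(to), "increasing",
    ifelse(classified(from) & uncertain(to), "decreasing", "neither"))
}

#' First and last chronological category per variant
#'
#' The endpoints used for transition (Sankey) tables: each variant's
#' category when it first entered the series and its final category.
#'
#' @param timelines Long timeline data.frame (NA categories ignored).
#' @param database Optional database filter.
#' @return data.frame (id, first, last).
#' @export
first_last_transition <- function(timelines, database = NULL) {
  tl <- timelines[!is.na(timelines$category), , drop = FALSE]
  if (!is.null(database)) tl <- tl[tl$database == database, , drop = FALSE]
  if (nrow(tl) == 0L) {
    return(data.frame(id = character(0), first = character(0),
      last = character(0), stringsAsFactors = FALSE))
  }
  tl <- tl[order(tl$id, as.Date(tl$date)), , drop = FALSE]
  out <- do.call(rbind, lapply(split(tl, tl$id), function(d) {
    data.frame(id = d$id[1L], first = d$category[1L],
      last = d$category[nrow(d)], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Variant-months of exposure in a set of categories
#'
#' Sums, over the months of the monthly-downsampled series inside
#' `window`, the number of variants whose category that month is in
#' `category_filter`. Two variants classified for one month and one
#' variant classified for two months are both 2 variant-months.
#'
#' @param timelines Long timeline data.frame.
#' @param category_filter Character vector of ladder levels.
#' @param window `c(start, end)` dates (inclusive on the representative
#'   snapshot date), default the audit window 2015-06-15 to 2020-12-31.
#' @param database Optional database filter.
#' @param monthly_rule Passed to [downsample_monthly()].
#' @return Integer variant-month count.
#' @export
variant_months <- function(timelines, category_filter,
                           window = c("2015-06-15", "2020-12-31"),
                           database = NULL, monthly_rule = "last") {
  tl <- timelines
  if (!is.null(database)) tl <- tl[tl$database == database, , drop = FALSE]
  tl <- monthly_timeline(tl, rule = monthly_rule)
  d <- as.Date(tl$date)
  keep <- d >= as.Date(window[1L]) & d <= as.Date(window[2L]) &
    tl$category %in% category_filter
  sum(keep)
}

#' Reclassification rate per variant-month with a Wald interval
#'
#' `rate = n_events / n_variant_months`; the 95% interval is
#' `rate +/- 1.96 * sqrt(rate * (1 - rate) / n_variant_months)`, with the
#' lower bound clipped at 0. Zero exposure yields NA sentinels.
#'
#' @param n_events Reclassification count.
#' @param n_variant_months Variant-months of the source category.
#' @param z Normal quantile, default 1.96.
#' @return data.frame (rate, ci_low, ci_high, n_events,
#'   n_variant_months).
#' @export
reclass_rate <- function(n_events, n_variant_months, z = 1.96) {
  if (n_variant_months <= 0) {
    return(data.frame(rate = NA_real_, ci_low = NA_real_,
      ci_high = NA_real_, n_events = n_events, n_variant_months = 0))
  }
  p <- n_events / n_variant_months
  half <- z * sqrt(p * (1 - p) / n_variant_months)
  data.frame(rate = p, ci_low = max(0, p - half), ci_high = p + half,
    n_events = n_events, n_variant_months = n_variant_months)
}

#' Compare reclassification rates across ancestries
#'
#' Omnibus r x 2 test on reclassification counts against variant-months of
#' the source category per ancestry, followed by one-sided 2x2 tests for
#' every ordered pair of ancestries (is A's rate higher than B's).
#' Zero-exposure ancestries are excluded with a log message; every test is
#' recorded in the ledger.
#'
#' @param n_events Named vector: reclassifications per ancestry.
#' @param n_variant_months Named vector: source-category variant-months
#'   per ancestry.
#' @param ledger A [new_test_ledger()].
#' @param follow_alpha Nominal omnibus level triggering pairwise tests.
#' @return list(rates = per-ancestry [reclass_rate()] table, omnibus,
#'   pairwise = data.frame(higher, lower, p) or NULL).
#' @export
compare_ancestry_rates <- function(n_events, n_variant_months,
                                   ledger = new_test_ledger(),
                                   follow_alpha = 0.05) {
  ancs <- names(n_variant_months)
  ok <- n_variant_months > 0
  if (any(!ok)) {
    audit_msg("excluding zero-exposure ancestries: ",
      paste(ancs[!ok], collapse = ", "))
  }
  ancs <- ancs[ok]
  ev <- n_events[ancs]
  ev[is.na(ev)] <- 0
  vm <- n_variant_months[ancs]
  rates <- do.call(rbind, lapply(ancs, function(a) {
    cbind(ancestry = a, reclass_rate(ev[[a]], vm[[a]]))
  }))
  tab <- cbind(events = as.integer(ev), variant_months = as.integer(vm))
  rownames(tab) <- ancs
  omni <- omnibus_rxc(tab)
  record_test(ledger, "rate omnibus")
  pairwise <- NULL
  if (omni$p_value < follow_alpha && length(ancs) >= 2L) {
    pairs <- expand.grid(higher = ancs, lower = ancs,
      stringsAsFactors = FALSE)
    pairs <- pairs[pairs$higher != pairs$lower, , drop = FALSE]
    pairwise <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      a <- pairs$higher[i]; b <- pairs$lower[i]
      t2 <- matrix(c(ev[[a]], vm[[a]], ev[[b]], vm[[b]]), 2L,
        byrow = TRUE)
      record_test(ledger, paste0("pairwise rate ", a, ">", b))
      data.frame(higher = a, lower = b,
        p = fisher_2x2(t2, "greater"), stringsAsFactors = FALSE)
    }))
  }
  list(rates = rates, omnibus = omni, pairwise = pairwise)
}

#' Collapse ClinVar star levels for cross-database comparability
#'
#' Maps P/LP_k to "P/LP" and B/LB_k to "B/LB" so the ClinVar ladder is
#' comparable with the star-less HGMD ladder.
#'
#' @param category Character vector of ClinVar ladder levels.
#' @return Collapsed categories.
#' @export
collapse_star_levels <- function(category) {
  out <- sub("^(P/LP|B/LB)_[0-3]$", "\\1", category)
  out
}
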