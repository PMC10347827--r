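# End-to-end audit orchestration from a single declarative config:
# ingest -> BA1 filter -> burden -> skew statistics -> recategorization,
# with stage-granular logging, TSV outputs and a JSON manifest.

#' Read an audit run configuration
#'
#' @param path YAML (or JSON) config file.
#' @return Config list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$config_path <- path
  cfg
}

#' Validate an audit run configuration without running it
#'
#' Checks referenced paths, the BA1 rule year, dialect/date coherence and
#' option values; returns diagnostics instead of erroring.
#'
#' @param config Config list (see [read_config()]): fields `panel`,
#'   `cohort_vcf`, `sample_sheet`, `snapshots` (named list per database of
#'   list(files, dates, dialect)), `frequency`, `ba1_year`
#'   (2015 | 2018 | "none"), `out_dir`, optional `sets`, `window`,
#'   `allowlist`, `options` (monthly_rule, unphased, star_override),
#'   `cutover`.
#' @return data.frame (level = "error"|"warning", message); zero rows for
#'   a clean config.
#' @export
validate_config <- function(config) {
  diags <- list()
  add <- function(level, msg) {
    diags[[length(diags) + 1L]] <<- data.frame(level = level,
      message = msg, stringsAsFactors = FALSE)
  }
  for (f in c("panel", "cohort_vcf", "sample_sheet")) {
    if (is.null(config[[f]])) add("error", paste0("missing field: ", f))
    else if (!file.exists(config[[f]])) {
      add("error", paste0(f, " not found: ", config[[f]]))
    }
  }
  ba1 <- config$ba1_year %||% "none"
  if (!as.character(ba1) %in% c("2015", "2018", "none")) {
    add("error", paste0("ba1_year must be 2015, 2018 or none, got: ", ba1))
  }
  if (as.character(ba1) != "none" && is.null(config$frequency)) {
    add("error", "BA1 filtering enabled but no frequency table configured")
  }
  if (!is.null(config$frequency) && !file.exists(config$frequency)) {
    add("error", paste0("frequency table not found: ", config$frequency))
  }
  cutover <- as.Date(config$cutover %||% "2015-06-15")
  for (db in names(config$snapshots)) {
    sn <- config$snapshots[[db]]
    missing <- !file.exists(unlist(sn$files))
    if (any(missing)) {
      add("error", paste0(db, ": ", sum(missing), " snapshot files missing"))
    }
    if (length(sn$files) != length(sn$dates)) {
      add("error", paste0(db, ": files/dates length mismatch"))
    }
    if (identical(sn$dialect, "archive1") &&
        any(as.Date(unlist(sn$dates)) >= cutover)) {
      add("warning",
        paste0(db, ": archive-1 snapshots dated on/after the cutover"))
    }
  }
  mr <- config$options$monthly_rule %||% "last"
  if (!mr %in% c("last", "first", "nearest_end")) {
    add("error", paste0("unknown monthly_rule: ", mr))
  }
  if (length(diags) == 0L) {
    return(data.frame(level = character(0), message = character(0),
      stringsAsFactors = FALSE))
  }
  do.call(rbind, diags)
}

# snapshot file table for build_timelines from the config
.snapshot_files <- function(config) {
  do.call(rbind, lapply(names(config$snapshots), function(db) {
    sn <- config$snapshots[[db]]
    dialect <- unlist(sn$dialect)
    files <- unlist(sn$files)
    dates <- unlist(sn$dates)
    if (length(dialect) == 1L && dialect == "clinvar_auto") {
      cutover <- as.Date(config$cutover %||% "2015-06-15")
      dialect <- ifelse(as.Date(dates) < cutover, "archive1", "archive2")
    }
    data.frame(path = files, date = dates,
      dialect = rep_len(dialect, length(files)), stringsAsFactors = FALSE)
  }))
}

#' Run the full classification audit from a config
#'
#' Stages, in order: snapshot ingest and timeline construction (with
#' optional condition filter and star overrides), BA1 frequency filtering,
#' cohort burden scan per variant set and snapshot date with yearly
#' maxima, ancestry-skew statistics per non-zero yearly bar,
#' recategorization extraction with variant-months-normalized
#' reclassification rates per ancestry, and report emission. All outputs
#' are TSV/JSON under `config$out_dir`; reruns with an identical config
#' are byte-identical.
#'
#' @param config Config list (see [validate_config()]).
#' @return Invisibly, a list with every stage's tables and the manifest.
#' @export
run_audit <- function(config) {
  diags <- validate_config(config)
  if (any(diags$level == "error")) {
    stop("config validation failed:\n  ",
      paste(diags$message[diags$level == "error"], collapse = "\n  "))
  }
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  logf <- function(stage, ...) {
    log_lines <<- c(log_lines, paste0("[", stage, "] ", paste0(...)))
  }

  # --- ingest ---------------------------------------------------------
  panel <- read_panel(config$panel)
  cohort <- read_cohort(config$cohort_vcf, config$sample_sheet)
  logf("ingest", "cohort: ", nrow(cohort$samples), " samples, ",
    nrow(cohort$variants), " variants; panel: ", nrow(panel), " genes")
  reference <- if (!is.null(config$reference)) {
    read_reference_fasta(config$reference)
  } else NULL
  star_override <- if (!is.null(config$options$star_override)) {
    read_tsv(config$options$star_override)
  } else NULL
  files <- .snapshot_files(config)
  timelines <- build_timelines(files, reference = reference,
    star_override = star_override,
    cutover = config$cutover %||% "2015-06-15")
  logf("ingest", nrow(timelines), " timeline entries from ",
    nrow(files), " snapshots")
  if (!is.null(config$allowlist)) {
    before <- nrow(timelines)
    timelines <- filter_condition(timelines, unlist(config$allowlist))
    logf("ingest", "condition filter: ", before, " -> ", nrow(timelines))
  }

  # --- BA1 ------------------------------------------------------------
  ba1_year <- as.character(config$ba1_year %||% "none")
  ba1_fun <- NULL
  ba1_removed <- NULL
  if (ba1_year != "none") {
    records <- read_frequency_table(config$frequency)
    all_ids <- unique(timelines$id)
    res <- if (ba1_year == "2015") {
      apply_ba1_2015(all_ids, records)
    } else {
      apply_ba1_2018(all_ids, records)
    }
    ba1_removed <- res$removed
    removed_ids <- unique(ba1_removed$id)
    ba1_fun <- function(ids, date) setdiff(ids, removed_ids)
    logf("ba1", "rule ", ba1_year, ": removed ", length(removed_ids),
      " of ", length(all_ids), " variants")
  }

  # --- burden ---------------------------------------------------------
  sets <- unlist(config$sets) %||% c("select_clinvar", "full_clinvar",
    "select_hgmd", "full_hgmd")
  sets <- sets[vapply(sets, function(s) {
    db <- if (grepl("hgmd", s)) "hgmd" else "clinvar"
    db %in% unique(timelines$database)
  }, logical(1L))]
  burden <- audit_burden(cohort, timelines, panel, sets = sets,
    ba1 = ba1_fun, unphased = config$options$unphased %||% "skip")
  logf("burden", nrow(burden$calls), " affected calls; ",
    NROW(burden$summary), " yearly bars")

  # --- skew statistics ------------------------------------------------
  ledger <- new_test_ledger()
  cohort_counts <- table(cohort$samples$ancestry)
  cohort_counts <- stats::setNames(as.integer(cohort_counts),
    names(cohort_counts))
  skew_rows <- list()
  skew_results <- list()
  if (NROW(burden$summary) > 0L) {
    for (i in seq_len(nrow(burden$summary))) {
      row <- burden$summary[i, ]
      if (row$n_affected == 0L) next  # zero bars are not tested
      aff <- stats::setNames(
        as.integer(row[paste0("n_", names(cohort_counts))]),
        names(cohort_counts))
      label <- paste0(row$set_name, " ", row$year)
      res <- ancestry_skew_tests(aff, cohort_counts, ledger = ledger,
        label = label)
      skew_results[[label]] <- res
      base <- data.frame(set_name = row$set_name, year = row$year,
        test = "omnibus", ancestry = "ALL", p = res$omnibus$p_value,
        method = res$omnibus$method, odds_ratio = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, stringsAsFactors = FALSE)
      skew_rows[[length(skew_rows) + 1L]] <- base
      if (!is.null(res$per_population)) {
        pp <- res$per_population
        skew_rows[[length(skew_rows) + 1L]] <- data.frame(
          set_name = row$set_name, year = row$year, test = "per_population",
          ancestry = pp$ancestry, p = pp$p, method = "exact",
          odds_ratio = pp$odds_ratio, ci_low = pp$ci_low,
          ci_high = pp$ci_high, stringsAsFactors = FALSE)
      }
    }
  }
  skew <- if (length(skew_rows) > 0L) do.call(rbind, skew_rows) else NULL

  # --- recategorization ----------------------------------------------
  monthly_rule <- config$options$monthly_rule %||% "last"
  window <- unlist(config$window) %||% c("2015-06-15", "2020-12-31")
  events <- list(); first_last <- list(); rate_rows <- list()
  rate_comparison <- NULL
  ancestry_map <- NULL
  if (!is.null(config$frequency)) {
    records <- read_frequency_table(config$frequency)
    pops <- unique(records[records$dataset == "gnomad" &
      records$population != "ALL", c("population", "n")])
    floor_ <- compute_maf_floor(stats::setNames(pops$n, pops$population))
    ancestry_map <- assign_ancestry(floor_mafs(records, floor_))
    logf("recat", "ancestry assignment: ",
      sum(ancestry_map$ancestry != "none"), " of ", nrow(ancestry_map),
      " variants assignable (floor ", signif(floor_, 4), ")")
  }
  for (db in intersect(c("clinvar", "hgmd"), unique(timelines$database))) {
    ev <- extract_events(timelines, db, monthly_rule = monthly_rule)
    ev$database <- db
    events[[db]] <- ev
    fl <- first_last_transition(timelines, db)
    fl$database <- db
    first_last[[db]] <- fl
    logf("recat", db, ": ", nrow(ev), " events, ",
      sum(ev$is_reclassification), " reclassifications")
  }
  ev_all <- do.call(rbind, events)
  fl_all <- do.call(rbind, first_last)

  # ancestry-normalized decreasing-confidence reclassification rates
  if (!is.null(ancestry_map) && "clinvar" %in% names(events)) {
    tl_cl <- timelines[timelines$database == "clinvar", , drop = FALSE]
    source_cats <- grep("^(P/LP|B/LB)", clinvar_ladder(), value = TRUE)
    ancs <- sort(unique(ancestry_map$ancestry[ancestry_map$ancestry !=
      "none"]))
    ev_cl <- events$clinvar
    ev_cl$ancestry <- ancestry_map$ancestry[match(ev_cl$id,
      ancestry_map$id)]
    n_ev <- n_vm <- stats::setNames(numeric(length(ancs)), ancs)
    for (a in ancs) {
      ids_a <- ancestry_map$id[ancestry_map$ancestry == a]
      n_ev[a] <- sum(ev_cl$ancestry %in% a &
        ev_cl$confidence_change == "decreasing" &
        ev_cl$is_reclassification, na.rm = TRUE)
      n_vm[a] <- variant_months(tl_cl[tl_cl$id %in% ids_a, , drop = FALSE],
        source_cats, window = window, monthly_rule = monthly_rule)
    }
    if (any(n_vm > 0)) {
      rate_comparison <- compare_ancestry_rates(n_ev, n_vm,
        ledger = ledger)
    }
  }

  threshold <- bonferroni(0.05, max(ledger$n, 1L))
  if (!is.null(skew)) skew$significant <- skew$p < threshold
  logf("stats", ledger$n, " tests performed; Bonferroni threshold ",
    signif(threshold, 2))

  # --- emit -----------------------------------------------------------
  paths <- list()
  emit <- function(obj, name) {
    if (is.null(obj) || NROW(obj) == 0L) return(invisible(NULL))
    p <- file.path(out_dir, name)
    write_tsv(obj, p)
    paths[[name]] <<- p
  }
  emit(burden$calls, "affected_calls.tsv")
  emit(burden$summary, "burden_summary.tsv")
  emit(ba1_removed, "ba1_removed.tsv")
  emit(skew, "skew_tests.tsv")
  emit(ev_all, "events.tsv")
  emit(fl_all, "first_last.tsv")
  if (!is.null(fl_all) && !is.null(ancestry_map)) {
    links <- fl_all
    links$ancestry <- ancestry_map$ancestry[match(links$id,
      ancestry_map$id)]
    links$count <- 1L
    links <- stats::aggregate(count ~ database + first + last + ancestry,
      data = links, FUN = sum)
    emit(links, "sankey_links.tsv")
  }
  if (!is.null(rate_comparison)) {
    emit(rate_comparison$rates, "reclass_rates.tsv")
    if (!is.null(rate_comparison$pairwise)) {
      emit(rate_comparison$pairwise, "rate_pairwise.tsv")
    }
  }

  inputs <- unlist(c(config$panel, config$cohort_vcf, config$sample_sheet,
    config$frequency,
    lapply(config$snapshots, function(s) unlist(s$files))))
  manifest <- list(
    package_version = as.character(utils::packageVersion("classaudit")),
    config = config[setdiff(names(config), "config_path")],
    inputs = lapply(stats::setNames(as.list(inputs), basename(inputs)),
      function(f) unname(tools::md5sum(f))),
    n_tests = ledger$n,
    bonferroni_threshold = threshold)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "log.txt"))

  invisible(list(burden = burden, skew = skew, skew_results = skew_results,
    events = ev_all, first_last = fl_all, ba1_removed = ba1_removed,
    rate_comparison = rate_comparison, test_ledger = ledger,
    bonferroni_threshold = threshold, timelines = timelines,
    manifest = manifest, out_dir = out_dir, paths = paths))
}

#' Write a run config for a generated study bundle
#'
#' Convenience for tests and drivers: builds the config list pointing at a
#' [gen_study()] output directory.
#'
#' @param study List from [gen_study()].
#' @param out_dir Output directory for [run_audit()].
#' @param ba1_year 2015, 2018 or "none".
#' @param ... Extra config fields (options, window, sets, allowlist).
#' @return Config list.
#' @export
study_config <- function(study, out_dir, ba1_year = 2015, ...) {
  cfg <- list(
    panel = study$paths$panel,
    cohort_vcf = study$paths$cohort_vcf,
    sample_sheet = study$paths$sample_sheet,
    frequency = study$paths$frequency,
    snapshots = list(
      clinvar = list(files = study$clinvar$files$path,
        dates = study$clinvar$files$date,
        dialect = study$clinvar$files$dialect),
      hgmd = list(files = study$hgmd$files$path,
        dates = study$hgmd$files$date,
        dialect = "hgmd")),
    ba1_year = ba1_year,
    out_dir = out_dir)
  utils::modifyList(cfg, list(...))
}
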