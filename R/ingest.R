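# Snapshot ingest: parse dated classification snapshots in the three
# dialects, normalize variant identities, map raw labels onto the category
# ladders and build per-variant classification timelines.

#' Read one ClinVar-dialect snapshot VCF
#'
#' Multiallelic records are split into biallelic keys; records that are
#' somatic-only or have a null alt allele are dropped. Archive-1 clinical
#' significance is a list of per-submission numeric codes (aggregated with
#' [infer_conflicting()]); archive-2 carries one aggregate label. Review
#' stars for archive-1 snapshots dated before `cutover` are unreliable and
#' stored as NA (excluded from star-dependent set selection).
#'
#' @param path Snapshot VCF path.
#' @param dialect "archive1" or "archive2".
#' @param date Snapshot date (ISO-8601).
#' @param cutover Review-star reliability boundary, default "2015-06-15".
#' @param info_keys Named list of INFO key names (sig, rev, cond).
#' @return data.frame: chrom, pos, ref, alt, id, database, dialect, date,
#'   tier, stars, sub_tiers, sub_stars, condition.
#' @export
read_snapshot_vcf <- function(path, dialect = c("archive2", "archive1"),
                              date, cutover = "2015-06-15",
                              info_keys = list(sig = "CLNSIG",
                                rev = "CLNREVSTAT", cond = "CLNDN")) {
  dialect <- match.arg(dialect)
  date <- as.Date(date)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(empty_snapshot())
  sig <- vcfR::extract.info(vcf, element = info_keys$sig)
  rev <- vcfR::extract.info(vcf, element = info_keys$rev)
  cond <- vcfR::extract.info(vcf, element = info_keys$cond)
  origin <- vcfR::extract.info(vcf, element = "CLNORIGIN")
  somatic <- grepl("SOMATIC", fix$INFO %||% "", fixed = TRUE) |
    (!is.na(origin) & origin == "2")

  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i] %||% ".", ",", fixed = TRUE)[[1]]
    for (alt in alts) {
      if (is.na(alt) || alt %in% c(".", "", "N") || somatic[i]) next
      if (dialect == "archive1") {
        codes <- strsplit(sig[i] %||% "", "[,|]")[[1]]
        tiers <- map_archive1_class(codes)
        tiers <- tiers[!is.na(tiers)]
        if (length(tiers) == 0L) next  # skip-and-log contract
        tier <- infer_conflicting(tiers)
        if (date < as.Date(cutover)) {
          sub_stars <- rep(NA_integer_, length(tiers))
        } else {
          toks <- strsplit(rev[i] %||% "", ",", fixed = TRUE)[[1]]
          st <- map_review_stars(paste(toks, collapse = ","), archive = 1)
          sub_stars <- rep(st, length(tiers))
        }
        stars <- if (all(is.na(sub_stars))) NA_integer_ else
          max(sub_stars, na.rm = TRUE)
        sub_tiers <- tiers
      } else {
        tier <- map_archive2_class(sig[i])
        if (is.na(tier)) next
        stars <- map_review_stars(rev[i], archive = 2)
        sub_tiers <- tier
        sub_stars <- stars
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alt,
        tier = tier, stars = stars,
        sub_tiers = paste(sub_tiers, collapse = ","),
        sub_stars = paste(sub_stars, collapse = ","),
        condition = if (is.na(cond[i]) || !nzchar(cond[i]))
          "not provided" else gsub("_", " ", cond[i]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty_snapshot())
  out <- do.call(rbind, rows)
  out$id <- key_id(out$chrom, out$pos, out$ref, out$alt)
  out$database <- "clinvar"
  out$dialect <- dialect
  out$date <- as.character(date)
  out$category <- NA_character_   # resolved in build_timelines
  out[, snapshot_cols()]
}

snapshot_cols <- function() {
  c("chrom", "pos", "ref", "alt", "id", "database", "dialect", "date",
    "tier", "stars", "sub_tiers", "sub_stars", "condition", "category")
}

empty_snapshot <- function() {
  out <- data.frame(chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0), id = character(0),
    database = character(0), dialect = character(0), date = character(0),
    tier = character(0), stars = integer(0), sub_tiers = character(0),
    sub_stars = character(0), condition = character(0),
    category = character(0), stringsAsFactors = FALSE)
  out
}

#' Read one HGMD-dialect snapshot TSV
#'
#' Expected columns: chrom, pos, ref, alt, class. Variants listed more than
#' once (or with comma-joined labels) resolve to the most severe label via
#' [map_hgmd_class()].
#'
#' @param path TSV path.
#' @param date Snapshot date.
#' @return data.frame in the common snapshot layout; `category` carries the
#'   HGMD label.
#' @export
read_snapshot_hgmd <- function(path, date) {
  raw <- read_tsv(path)
  stopifnot(all(c("chrom", "pos", "ref", "alt", "class") %in% names(raw)))
  if (nrow(raw) == 0L) return(empty_snapshot())
  raw$id <- key_id(raw$chrom, raw$pos, raw$ref, raw$alt)
  rows <- lapply(split(raw, raw$id), function(d) {
    labels <- unlist(strsplit(d$class, ",", fixed = TRUE))
    lab <- map_hgmd_class(labels)
    if (is.na(lab)) return(NULL)
    data.frame(chrom = d$chrom[1L], pos = d$pos[1L], ref = d$ref[1L],
      alt = d$alt[1L], id = d$id[1L], database = "hgmd", dialect = "hgmd",
      date = as.character(as.Date(date)), tier = NA_character_,
      stars = NA_integer_, sub_tiers = NA_character_,
      sub_stars = NA_character_, condition = "not provided",
      category = lab, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_snapshot())
  rownames(out) <- NULL
  out[, snapshot_cols()]
}

#' Ingest a whole snapshot series into classification timelines
#'
#' @param files data.frame with columns path, date, dialect (as returned in
#'   `gen_snapshot_series()$files`), or a list of such frames.
#' @param reference Optional named reference sequences for key
#'   normalization (see [normalize_table()]).
#' @param star_override Optional data.frame (id, stars): per-variant review
#'   stars asserted by manual curation, applied to every ClinVar entry of
#'   that variant.
#' @param ... Passed to the per-file readers (e.g. `cutover`, `info_keys`).
#' @return Long timeline data.frame, one row per (variant, date), ordered
#'   by id then date, with the ladder `category` resolved
#'   (NA when unplaceable). ClinVar categories come from
#'   [clinvar_category()]; HGMD rows keep their label.
#' @export
build_timelines <- function(files, reference = NULL, star_override = NULL,
                            ...) {
  if (is.list(files) && !is.data.frame(files)) {
    files <- do.call(rbind, files)
  }
  snaps <- lapply(seq_len(nrow(files)), function(i) {
    if (files$dialect[i] == "hgmd") {
      read_snapshot_hgmd(files$path[i], files$date[i])
    } else {
      read_snapshot_vcf(files$path[i], files$dialect[i], files$date[i],
        ...)
    }
  })
  tl <- do.call(rbind, snaps)
  if (nrow(tl) == 0L) return(tl)
  tl <- normalize_table(tl, reference)
  if (!is.null(star_override) && nrow(star_override) > 0L) {
    m <- match(tl$id, star_override$id)
    hit <- !is.na(m) & tl$database == "clinvar"
    tl$stars[hit] <- star_override$stars[m[hit]]
  }
  cl <- tl$database == "clinvar"
  tl$category[cl] <- clinvar_category(tl$tier[cl], tl$stars[cl])
  tl <- tl[order(tl$id, as.Date(tl$date)), , drop = FALSE]
  # one entry per (id, database, date): keep the last occurrence
  dup <- duplicated(tl[, c("id", "database", "date")], fromLast = TRUE)
  tl <- tl[!dup, , drop = FALSE]
  rownames(tl) <- NULL
  tl
}

#' Drop entries whose submitted condition is not an audited disorder
#'
#' Entries with condition "not provided" (or missing) are retained.
#'
#' @param entries Snapshot/timeline data.frame with a `condition` column.
#' @param allowlist Character vector of audited disorder labels.
#' @return Filtered data.frame.
#' @export
filter_condition <- function(entries, allowlist) {
  keep <- is.na(entries$condition) |
    entries$condition == "not provided" |
    entries$condition %in% allowlist
  dropped <- sum(!keep)
  if (dropped > 0L) {
    audit_msg("condition filter: dropped ", dropped, " entries")
  }
  entries[keep, , drop = FALSE]
}

#' Entries of a timeline at one snapshot date
#'
#' @param timelines Long timeline data.frame.
#' @param date Snapshot date present in the series.
#' @param database Optional database filter ("clinvar"/"hgmd").
#' @return Rows of `timelines` at that date.
#' @export
snapshot_at <- function(timelines, date, database = NULL) {
  out <- timelines[timelines$date == as.character(as.Date(date)), ,
    drop = FALSE]
  if (!is.null(database)) out <- out[out$database == database, ,
    drop = FALSE]
  out
}

#' Select a variant set from a date-resolved snapshot
#'
#' * `select_clinvar`: Pathogenic with >= 1 review star, excluding variants
#'   that also carry a VUS/B/LB submission with >= 1 star (when submission
#'   detail is available; an aggregate Conflicting state always excludes).
#' * `full_clinvar`: tier P or LP; Conflicting excluded.
#' * `select_hgmd`: DM. `full_hgmd`: DM or DM?.
#'
#' @param snapshot One-date snapshot data.frame (see [snapshot_at()]).
#' @param set_name One of the four set labels.
#' @return Character vector of variant ids.
#' @export
select_variant_set <- function(snapshot,
                               set_name = c("select_clinvar",
                                 "full_clinvar", "select_hgmd",
                                 "full_hgmd")) {
  set_name <- match.arg(set_name)
  if (set_name %in% c("select_hgmd", "full_hgmd")) {
    s <- snapshot[snapshot$database == "hgmd", , drop = FALSE]
    want <- if (set_name == "select_hgmd") "DM" else c("DM", "DM?")
    return(unique(s$id[s$category %in% want]))
  }
  s <- snapshot[snapshot$database == "clinvar", , drop = FALSE]
  if (set_name == "full_clinvar") {
    return(unique(s$id[s$tier %in% c("P", "LP")]))
  }
  # select_clinvar, submission-level rule
  ok <- vapply(seq_len(nrow(s)), function(i) {
    tiers <- strsplit(s$sub_tiers[i], ",", fixed = TRUE)[[1]]
    stars <- suppressWarnings(as.integer(
      strsplit(s$sub_stars[i], ",", fixed = TRUE)[[1]]))
    stars <- rep_len(stars, length(tiers))
    p_ok <- any(tiers == "P" & !is.na(stars) & stars >= 1L)
    conflict <- any(tiers %in% c("VUS", "B", "LB") & !is.na(stars) &
      stars >= 1L)
    p_ok && !conflict
  }, logical(1L))
  unique(s$id[ok])
}
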