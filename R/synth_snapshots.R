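# Synthetic dated classification snapshot series in three dialects:
# archive-1.0-style ClinVar VCFs (numeric CLNSIG codes), archive-2.0-style
# ClinVar VCFs (string labels), and HGMD-style TSVs. Planted
# recategorizations are recorded in the ground-truth ledger.

# ladder token -> generator state (tier, stars) for ClinVar dialects
.token_state <- function(token, tier_choice = NULL) {
  if (token %in% hgmd_ladder()) {
    return(list(kind = "hgmd", label = token))
  }
  if (token == "VUS") return(list(kind = "clinvar", tier = "VUS", stars = 1L))
  if (token == "Conflicting") {
    return(list(kind = "clinvar", tier = "Conflicting", stars = 1L))
  }
  m <- regmatches(token, regexec("^(P/LP|B/LB)_([0-3])$", token))[[1]]
  if (length(m) == 0L) stop("unknown category token: ", token)
  tier <- tier_choice %||% if (m[2] == "P/LP") "P" else "B"
  list(kind = "clinvar", tier = tier, stars = as.integer(m[3]))
}

.a2_label <- c(P = "Pathogenic", LP = "Likely_pathogenic",
  B = "Benign", LB = "Likely_benign", VUS = "Uncertain_significance",
  Conflicting = "Conflicting_interpretations_of_pathogenicity")
.a2_status <- c(`0` = "no_assertion_criteria_provided",
  `1` = "criteria_provided,_single_submitter",
  `2` = "criteria_provided,_multiple_submitters,_no_conflicts",
  `3` = "reviewed_by_expert_panel")
.a1_code <- c(P = "5", LP = "4", B = "2", LB = "3", VUS = "0")
.a1_status <- c(`0` = "no_assertion", `1` = "single", `2` = "mult")

#' Generate a dated classification snapshot series with planted transitions
#'
#' Non-planted (background) variants keep a constant category across the
#' series; each planted transition flips its variant's category at the
#' first snapshot date on or after the transition date. A transition with
#' `via_removal = TRUE` additionally drops the variant from the snapshot
#' immediately preceding the transition, exercising the removal /
#' re-entry-under-a-new-category rule.
#'
#' @param panel Panel from [gen_panel()]; variants are placed inside panel
#'   genes.
#' @param dates Strictly increasing vector of snapshot dates (ISO-8601).
#' @param recat_spec data.frame with columns `from`, `to` (ladder tokens),
#'   `date`, optional `via_removal` (logical). One synthetic variant is
#'   created per row; its key is recorded in the ledger.
#' @param dialect "archive1", "archive2", "hgmd", or "clinvar_auto"
#'   (archive1 before `cutover`, archive2 from `cutover` on).
#' @param seed Integer seed.
#' @param dir Output directory for the snapshot files.
#' @param n_background Constant-category background variants.
#' @param extra_variants Optional data.frame (chrom,pos,ref,alt or id,
#'   category, optional tier, condition) of variants to carry at a constant
#'   category — used to expose cohort-planted pathogenic variants to the
#'   classification series.
#' @param cutover Archive-1 to archive-2 cutover date (also the review-star
#'   reliability boundary), default "2015-06-15".
#' @param condition Default condition string for emitted records.
#' @return list with `files` (data.frame path, date, dialect), `variants`
#'   (per-variant constant/planted state) and `ledger` (planted_recats +
#'   seed).
#' @export
gen_snapshot_series <- function(panel, dates, recat_spec = NULL,
                                dialect = c("archive2", "archive1", "hgmd",
                                            "clinvar_auto"),
                                seed = 1L, dir = tempfile("snapshots"),
                                n_background = 20L, extra_variants = NULL,
                                cutover = "2015-06-15",
                                condition = "not provided") {
  dialect <- match.arg(dialect)
  dates <- as.Date(dates)
  if (length(dates) == 0L || any(diff(dates) <= 0)) {
    stop("snapshot dates must be strictly increasing")
  }
  cutover <- as.Date(cutover)
  if (dialect == "archive1" && any(dates >= cutover)) {
    stop("archive-1 dialect is only allowed for dates before the cutover (",
      format(cutover), ")")
  }
  if (is.null(recat_spec)) {
    recat_spec <- data.frame(from = character(0), to = character(0),
      date = character(0), stringsAsFactors = FALSE)
  }
  if (nrow(recat_spec) > 0L) {
    rd <- as.Date(recat_spec$date)
    if (any(rd <= min(dates) | rd > max(dates))) {
      stop("planted transition dated outside the snapshot series")
    }
    if (is.null(recat_spec$via_removal)) recat_spec$via_removal <- FALSE
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  is_hgmd <- dialect == "hgmd"

  with_seed(seed, {
    # background variants with constant categories
    bg_tokens <- if (is_hgmd) {
      sample(c("DM", "DM?", "DFP", "DP"), n_background, replace = TRUE,
        prob = c(0.5, 0.25, 0.15, 0.1))
    } else {
      sample(c("P/LP_0", "P/LP_1", "P/LP_2", "VUS", "Conflicting",
        "B/LB_1", "B/LB_0"), n_background, replace = TRUE)
    }
    genes <- panel$gene
    mk_variant <- local({
      counter <- new.env()
      function() {
        g <- panel[panel$gene == sample(genes, 1L), , drop = FALSE]
        k <- (counter[[g$gene]] <- (counter[[g$gene]] %||% 0L) + 1L)
        pos <- g$end - 10L * k    # top of the gene: clear of cohort variants
        if (pos <= g$start) stop("gene ", g$gene, " exhausted")
        refalt <- sample(c("A", "C", "G", "T"), 2L)
        data.frame(chrom = g$chrom, pos = pos, ref = refalt[1L],
          alt = refalt[2L], stringsAsFactors = FALSE)
      }
    })

    vrows <- list()
    add_row <- function(v, from, to, change_date, via_removal, tier,
                        cond) {
      vrows[[length(vrows) + 1L]] <<- data.frame(
        chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
        id = key_id(v$chrom, v$pos, v$ref, v$alt),
        from = from, to = to,
        change_date = if (is.na(change_date)) NA_character_ else
          as.character(change_date),
        via_removal = via_removal, tier = tier %||% NA_character_,
        condition = cond, stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_background)) {
      add_row(mk_variant(), bg_tokens[i], bg_tokens[i], NA, FALSE, NULL,
        condition)
    }
    if (!is.null(extra_variants) && nrow(extra_variants) > 0L) {
      ev <- extra_variants
      if (!all(c("chrom", "pos", "ref", "alt") %in% names(ev))) {
        ev <- cbind(parse_key(ev$id),
          ev[, setdiff(names(ev), c("id", "chrom", "pos", "ref", "alt")),
             drop = FALSE])
      }
      for (i in seq_len(nrow(ev))) {
        add_row(ev[i, ], ev$category[i], ev$category[i], NA, FALSE,
          if ("tier" %in% names(ev)) ev$tier[i] else NULL,
          if ("condition" %in% names(ev)) ev$condition[i] else condition)
      }
    }
    planted <- NULL
    if (nrow(recat_spec) > 0L) {
      planted <- do.call(rbind, lapply(seq_len(nrow(recat_spec)),
        function(i) {
          v <- mk_variant()
          add_row(v, recat_spec$from[i], recat_spec$to[i],
            as.Date(recat_spec$date[i]), recat_spec$via_removal[i], NULL,
            condition)
          data.frame(id = key_id(v$chrom, v$pos, v$ref, v$alt),
            date = as.character(as.Date(recat_spec$date[i])),
            from = recat_spec$from[i], to = recat_spec$to[i],
            via_removal = recat_spec$via_removal[i],
            stringsAsFactors = FALSE)
        }))
    } else {
      planted <- data.frame(id = character(0), date = character(0),
        from = character(0), to = character(0),
        via_removal = logical(0), stringsAsFactors = FALSE)
    }
    variants <- do.call(rbind, vrows)
    variants <- variants[order(match(variants$chrom, unique(panel$chrom)),
      variants$pos), , drop = FALSE]
    rownames(variants) <- NULL
    stopifnot(!anyDuplicated(variants$id))

    files <- do.call(rbind, lapply(seq_along(dates), function(di) {
      d <- dates[di]
      dia <- if (dialect == "clinvar_auto") {
        if (d < cutover) "archive1" else "archive2"
      } else dialect
      # category of each variant at this date
      tok <- ifelse(is.na(variants$change_date) |
          d < as.Date(variants$change_date),
        variants$from, variants$to)
      keep <- rep(TRUE, nrow(variants))
      # removal: absent at the snapshot immediately preceding the change
      for (i in which(variants$via_removal)) {
        pre <- dates[dates < as.Date(variants$change_date[i])]
        if (length(pre) > 0L && d == max(pre)) keep[i] <- FALSE
      }
      v <- variants[keep, , drop = FALSE]
      tok <- tok[keep]
      ext <- if (dia == "hgmd") "tsv" else "vcf"
      path <- file.path(dir, sprintf("snapshot_%s_%s.%s", dia,
        format(d, "%Y%m%d"), ext))
      if (dia == "hgmd") {
        keep2 <- tok %in% hgmd_ladder()
        write_tsv(data.frame(chrom = v$chrom[keep2], pos = v$pos[keep2],
          ref = v$ref[keep2], alt = v$alt[keep2], class = tok[keep2],
          stringsAsFactors = FALSE), path)
      } else {
        write_snapshot_vcf(v, tok, path, dia)
      }
      data.frame(path = path, date = as.character(d), dialect = dia,
        stringsAsFactors = FALSE)
    }))

    list(files = files, variants = variants,
      ledger = list(planted_recats = planted,
        seeds = list(snapshots = seed)))
  })
}

# emit one ClinVar-dialect snapshot VCF
write_snapshot_vcf <- function(v, tokens, path, dialect) {
  info <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    st <- .token_state(tokens[i],
      tier_choice = if (!is.na(v$tier[i])) v$tier[i] else NULL)
    if (st$kind != "clinvar") stop("HGMD token in ClinVar dialect: ",
      tokens[i])
    cond <- gsub("[;= ]", "_", v$condition[i])
    if (dialect == "archive2") {
      info[i] <- sprintf("CLNSIG=%s;CLNREVSTAT=%s;CLNDN=%s",
        .a2_label[[st$tier]], .a2_status[[as.character(st$stars)]], cond)
    } else {
      if (st$tier == "Conflicting") {
        codes <- "5,0"; stats_ <- "single,single"
      } else {
        codes <- .a1_code[[st$tier]]
        stats_ <- .a1_status[[as.character(min(st$stars, 2L))]]
      }
      info[i] <- sprintf("CLNSIG=%s;CLNREVSTAT=%s;CLNDN=%s",
        codes, stats_, cond)
    }
  }
  hdr <- c("##fileformat=VCFv4.2",
    "##source=classaudit-synthetic",
    '##INFO=<ID=CLNSIG,Number=.,Type=String,Description="Clinical significance">',
    '##INFO=<ID=CLNREVSTAT,Number=.,Type=String,Description="Review status">',
    '##INFO=<ID=CLNDN,Number=.,Type=String,Description="Condition">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
      collapse = "\t"))
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", ".", info,
    sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
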