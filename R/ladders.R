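# Category ladders shared by ingest, burden detection and recategorization.
#
# ClinVar aggregate states are placed on a 10-level ladder ordered from most
# benign to most pathogenic; review stars refine the two classified tiers.
# VUS and Conflicting sit between the tiers and are adjacent, unordered
# levels for confidence purposes (see recategorization).

#' The 10-level ClinVar category ladder
#'
#' Levels ordered from most benign to most pathogenic:
#' `B/LB_3 < B/LB_2 < B/LB_1 < B/LB_0 < VUS < Conflicting <
#'  P/LP_0 < P/LP_1 < P/LP_2 < P/LP_3`.
#' The suffix is the review-star count (3 = expert panel; "2+" review
#' status is stored as 2).
#'
#' @return Character vector of the 10 ladder levels in order.
#' @export
clinvar_ladder <- function() {
  c("B/LB_3", "B/LB_2", "B/LB_1", "B/LB_0", "VUS", "Conflicting",
    "P/LP_0", "P/LP_1", "P/LP_2", "P/LP_3")
}

#' The 5-level HGMD category ladder
#'
#' Severity order `DM > DM? > DFP > DP > R`; returned from least to most
#' severe so that ladder index increases with pathogenicity, matching
#' [clinvar_ladder()].
#'
#' @return Character vector `c("R","DP","DFP","DM?","DM")`.
#' @export
hgmd_ladder <- function() {
  c("R", "DP", "DFP", "DM?", "DM")
}

#' Ladder index of a category
#'
#' @param category Character vector of ladder levels.
#' @param database `"clinvar"` or `"hgmd"`.
#' @return Integer index within the database's ladder (NA if not a level).
#' @export
ladder_index <- function(category, database = c("clinvar", "hgmd")) {
  database <- match.arg(database)
  ladder <- if (database == "clinvar") clinvar_ladder() else hgmd_ladder()
  match(category, ladder)
}

#' Compose a ClinVar ladder level from tier and stars
#'
#' Tiers B/LB and P/LP require a star count; VUS and Conflicting carry none.
#' A B/LB or P/LP tier with missing stars (archive-1.0 records before the
#' review-star reliability cutover) yields NA: such entries cannot be placed
#' on the ladder and are excluded from star-dependent analyses.
#'
#' @param tier One of "B", "LB", "VUS", "Conflicting", "LP", "P" (vector ok).
#' @param stars Integer review stars (0-3), NA allowed.
#' @return Character vector of ladder levels (NA where unplaceable).
#' @export
clinvar_category <- function(tier, stars = NA_integer_) {
  n <- max(length(tier), length(stars))
  tier <- rep_len(as.character(tier), n)
  stars <- rep_len(as.integer(stars), n)
  out <- rep(NA_character_, n)
  out[tier %in% "VUS"] <- "VUS"
  out[tier %in% "Conflicting"] <- "Conflicting"
  bl <- tier %in% c("B", "LB") & !is.na(stars)
  out[bl] <- paste0("B/LB_", stars[bl])
  pl <- tier %in% c("P", "LP") & !is.na(stars)
  out[pl] <- paste0("P/LP_", stars[pl])
  bad <- !is.na(out) & !(out %in% c(clinvar_ladder(), "VUS", "Conflicting"))
  out[bad] <- NA_character_
  out
}

# major tier groups used for the reclassification (vs recategorization)
# distinction: P/LP, VUS/Conflicting, B/LB
major_tier <- function(category, database = "clinvar") {
  if (database == "hgmd") return(category)
  ifelse(grepl("^P/LP", category), "P/LP",
    ifelse(grepl("^B/LB", category), "B/LB",
      ifelse(category %in% c("VUS", "Conflicting"), "VUS/Conflicting",
        NA_character_)))
}

#' Map an archive-1.0 numeric clinical-significance code to a tier
#'
#' Recognized codes: "0" VUS, "2" Benign, "3" Likely Benign,
#' "4" Likely Pathogenic, "5" Pathogenic. Unrecognized codes map to the
#' unmapped sentinel NA (the record is skipped and logged, never an error).
#'
#' @param code Character vector of codes.
#' @return Character vector of tiers ("B","LB","VUS","LP","P") or NA.
#' @export
map_archive1_class <- function(code) {
  map <- c("0" = "VUS", "2" = "B", "3" = "LB", "4" = "LP", "5" = "P")
  out <- unname(map[as.character(code)])
  if (anyNA(out)) {
    audit_msg("archive-1 ingest: skipping unmapped significance code(s): ",
      paste(unique(code[is.na(out)]), collapse = ", "))
  }
  out
}

# archive-2.0 label -> tier lookup (exact tokens)
.archive2_map <- c(
  "Benign" = "B",
  "Benign/Likely_benign" = "B",
  "Likely_benign" = "LB",
  "Uncertain_significance" = "VUS",
  "Likely_pathogenic" = "LP",
  "Pathogenic/Likely_pathogenic" = "P",
  "Pathogenic" = "P",
  "Conflicting_interpretations_of_pathogenicity" = "Conflicting"
)

#' Map an archive-2.0 clinical-significance label to a tier
#'
#' Handles comma-separated multi-labels: if exactly one comma-separated
#' component is a recognized category the variant is assigned to it
#' (e.g. "Pathogenic,_risk_factor" is P); zero or two or more recognized
#' components yield the unmapped sentinel NA (skip-and-log).
#'
#' @param label Character vector of CLNSIG labels.
#' @return Character vector of tiers or NA.
#' @export
map_archive2_class <- function(label) {
  one <- function(lab) {
    if (is.na(lab)) return(NA_character_)
    hits <- .archive2_map[strsplit(lab, ",", fixed = TRUE)[[1]]]
    hits <- hits[!is.na(hits)]
    if (length(hits) == 1L) unname(hits) else NA_character_
  }
  out <- vapply(label, one, NA_character_, USE.NAMES = FALSE)
  if (anyNA(out)) {
    audit_msg("archive-2 ingest: skipping unmapped label(s): ",
      paste(unique(label[is.na(out)]), collapse = "; "))
  }
  out
}

#' Aggregate per-submission tiers, inferring Conflicting
#'
#' A variant is Conflicting when its submissions span two or more of the
#' three groups {B, LB}, {VUS}, {P, LP}; otherwise the single represented
#' group's most severe member is returned (P over LP, B over LB).
#'
#' @param tiers Character vector of per-submission tiers (non-empty).
#' @return A single tier or "Conflicting".
#' @export
infer_conflicting <- function(tiers) {
  tiers <- tiers[!is.na(tiers)]
  if (length(tiers) == 0L) stop("infer_conflicting: empty tier set")
  groups <- unique(ifelse(tiers %in% c("B", "LB"), "BLB",
    ifelse(tiers == "VUS", "VUS", "PLP")))
  if (length(groups) >= 2L) return("Conflicting")
  if (groups == "VUS") return("VUS")
  if (groups == "PLP") return(if ("P" %in% tiers) "P" else "LP")
  if ("B" %in% tiers) "B" else "LB"
}

.stars_map <- list(
  `1` = list(
    `0` = c("no_assertion_criteria_provided", "no_assertion_provided",
            "not", "no_criteria", "no_assertion"),
    `1` = c("criteria_provided", "conf", "single"),
    `2` = c("mult", "_multiple_submitters", "_no_conflicts")
  ),
  `2` = list(
    `0` = c("no_assertion_criteria_provided", "No_assertion_provided",
            "no_interpretation_for_the_single_variant"),
    `1` = c("criteria_provided", "_single_submitter",
            "_conflicting_interpretations"),
    `2` = c("_multiple_submitters", "_no_conflicts",
            "reviewed_by_expert_panel")
  )
)

#' Map a review-status string to grouped review stars
#'
#' Composite statuses (comma-joined tokens) score as the highest group any
#' token belongs to; "2+" (including expert panel) is stored as 2. A status
#' with no recognized token maps to 0 stars with a warning.
#'
#' @param status Character vector of review-status strings.
#' @param archive 1 or 2 (dialect-specific token groups).
#' @return Integer vector of stars (0, 1 or 2).
#' @export
map_review_stars <- function(status, archive = 2) {
  groups <- .stars_map[[as.character(archive)]]
  if (is.null(groups)) stop("unknown archive dialect: ", archive)
  one <- function(s) {
    if (is.na(s) || !nzchar(s)) return(0L)
    toks <- strsplit(s, ",", fixed = TRUE)[[1]]
    best <- -1L
    for (lev in c(0L, 1L, 2L)) {
      if (any(toks %in% groups[[as.character(lev)]])) best <- lev
    }
    if (best < 0L) {
      warning("unknown review status '", s, "', treating as 0 stars",
        call. = FALSE)
      best <- 0L
    }
    best
  }
  vapply(status, one, 0L, USE.NAMES = FALSE)
}

#' Resolve multiple HGMD labels to the most severe classification
#'
#' Severity order DM > DM? > DFP > DP > R. Unknown labels are dropped with
#' a log message; if none remain the unmapped sentinel NA is returned.
#'
#' @param labels Character vector of HGMD labels (non-empty).
#' @return A single label, or NA if none recognized.
#' @export
map_hgmd_class <- function(labels) {
  if (length(labels) == 0L) stop("map_hgmd_class: empty label set")
  known <- labels[labels %in% hgmd_ladder()]
  if (length(known) < length(labels)) {
    audit_msg("hgmd ingest: skipping unknown label(s): ",
      paste(setdiff(labels, hgmd_ladder()), collapse = ", "))
  }
  if (length(known) == 0L) return(NA_character_)
  hgmd_ladder()[max(match(known, hgmd_ladder()))]
}
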