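#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a canonical variant identifier
#'
#' Joins chromosome, position, reference and alternate allele into the
#' string key used to join databases, cohort genotypes and frequency tables.
#'
#' @param chrom Chromosome label.
#' @param pos 1-based position.
#' @param ref Reference allele.
#' @param alt Alternate allele.
#' @return Character vector of keys, `"chrom:pos:ref:alt"`.
#' @export
key_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Split canonical variant identifiers back into fields
#'
#' @param id Character vector of `"chrom:pos:ref:alt"` keys.
#' @return data.frame with columns chrom, pos, ref, alt, id.
#' @export
parse_key <- function(id) {
  parts <- strsplit(id, ":", fixed = TRUE)
  stopifnot(all(lengths(parts) == 4L))
  data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    pos = as.integer(vapply(parts, `[`, "", 2L)),
    ref = vapply(parts, `[`, "", 3L),
    alt = vapply(parts, `[`, "", 4L),
    id = id,
    stringsAsFactors = FALSE
  )
}

# First day of the calendar month containing each date.
month_floor <- function(date) {
  as.Date(format(as.Date(date), "%Y-%m-01"))
}

# "YYYY-MM" month token.
month_token <- function(date) {
  format(as.Date(date), "%Y-%m")
}

# Inclusive sequence of month tokens between two dates.
month_seq <- function(from, to) {
  if (as.Date(from) > as.Date(to)) return(character(0))
  format(seq(month_floor(from), month_floor(to), by = "month"), "%Y-%m")
}

# stage-tagged progress/warning messages, silenced via option
audit_msg <- function(...) {
  if (isTRUE(getOption("classaudit.quiet", TRUE))) return(invisible(NULL))
  message(...)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}
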