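# Variant identity normalization: left-aligned minimal representation,
# the precondition for joining classification databases, cohort genotypes
# and frequency tables on one key.

#' Normalize a variant to its minimal left-aligned representation
#'
#' Implements the standard trim/left-shift algorithm: the shared suffix is
#' trimmed; when either allele empties, the representation is extended
#' leftward from the reference context (left-alignment of indels); finally
#' the shared prefix is trimmed while both alleles keep at least one base.
#' SNVs pass through unchanged and the operation is idempotent.
#'
#' @param chrom Chromosome label.
#' @param pos 1-based position of `ref` within the chromosome.
#' @param ref Reference allele (must match the context).
#' @param alt Alternate allele (non-empty, different from `ref`).
#' @param context Reference sequence covering the variant locus.
#' @param context_start 1-based chromosome position of the first base of
#'   `context` (default 1).
#' @return A one-row data.frame (chrom, pos, ref, alt, id).
#' @export
normalize_variant <- function(chrom, pos, ref, alt, context,
                              context_start = 1L) {
  stopifnot(length(pos) == 1L, nchar(ref) >= 1L, nchar(alt) >= 1L)
  if (ref == alt) stop("ref and alt must differ")
  pos <- as.integer(pos)
  off <- pos - as.integer(context_start) + 1L
  if (off < 1L || off + nchar(ref) - 1L > nchar(context)) {
    stop("reference mismatch: context does not cover the variant locus")
  }
  if (substr(context, off, off + nchar(ref) - 1L) != ref) {
    stop("reference mismatch: ref allele disagrees with context")
  }
  last1 <- function(x) substr(x, nchar(x), nchar(x))
  repeat {
    if (nchar(ref) > 0L && nchar(alt) > 0L && last1(ref) == last1(alt)) {
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
    } else if (nchar(ref) == 0L || nchar(alt) == 0L) {
      if (off == 1L) {
        stop("reference mismatch: context too short to left-align variant")
      }
      off <- off - 1L
      pos <- pos - 1L
      base <- substr(context, off, off)
      ref <- paste0(base, ref)
      alt <- paste0(base, alt)
    } else {
      break
    }
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
    off <- off + 1L
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
    id = key_id(chrom, pos, ref, alt), stringsAsFactors = FALSE)
}

#' Normalize a table of variants against reference contexts
#'
#' @param variants data.frame with chrom, pos, ref, alt.
#' @param reference Named character vector (or list) of chromosome
#'   sequences, e.g. as read by [read_reference_fasta()]. Chromosomes
#'   absent from `reference` pass through untouched (already-normalized
#'   input is the common case).
#' @return The table with normalized chrom/pos/ref/alt and an `id` column.
#' @export
normalize_table <- function(variants, reference = NULL) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  if (!is.null(reference) && nrow(variants) > 0L) {
    for (i in seq_len(nrow(variants))) {
      ctx <- reference[[variants$chrom[i]]]
      if (is.null(ctx) || is.na(ctx)) next
      nv <- normalize_variant(variants$chrom[i], variants$pos[i],
        variants$ref[i], variants$alt[i], ctx)
      variants$pos[i] <- nv$pos
      variants$ref[i] <- nv$ref
      variants$alt[i] <- nv$alt
    }
  }
  variants$id <- key_id(variants$chrom, variants$pos,
    variants$ref, variants$alt)
  variants
}

#' Read reference context sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_reference_fasta <- function(path) {
  seqs <- seqinr::read.fasta(path, as.string = TRUE, seqtype = "DNA",
    forceDNAtolower = FALSE)
  out <- toupper(vapply(seqs, `[[`, "", 1L))
  names(out) <- names(seqs)
  out
}
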