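# Synthetic gene panel generator: stands in for a curated screened-disorder
# panel (autosomal-recessive genes plus X-linked genes).

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a synthetic gene panel
#'
#' Autosomal-recessive genes are placed on autosomes chr1-chr22 and X-linked
#' genes on chrX, in fixed non-overlapping 1-Mb slots so interval joins are
#' unambiguous. Deterministic for a fixed seed.
#'
#' @param n_autosomal Number of autosomal-recessive (AR) genes.
#' @param n_xlinked Number of X-linked (XL) genes.
#' @param seed Integer seed.
#' @return data.frame (gene, chrom, start, end, inheritance) with
#'   inheritance "AR" or "XL"; 1-based inclusive coordinates.
#' @export
gen_panel <- function(n_autosomal, n_xlinked, seed = 1L) {
  stopifnot(n_autosomal >= 0L, n_xlinked >= 0L)
  if (n_autosomal + n_xlinked == 0L) stop("empty panel")
  with_seed(seed, {
    rows <- list()
    if (n_autosomal > 0L) {
      chroms <- paste0("chr", sample(1:22, n_autosomal, replace = TRUE))
      for (i in seq_len(n_autosomal)) {
        slot <- sum(chroms[seq_len(i)] == chroms[i])  # per-chrom slot index
        start <- (slot - 1L) * 1000000L + sample(1000:50000, 1L)
        len <- sample(5000:40000, 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = sprintf("ARG%02d", i), chrom = chroms[i],
          start = start, end = start + len, inheritance = "AR",
          stringsAsFactors = FALSE)
      }
    }
    if (n_xlinked > 0L) {
      for (i in seq_len(n_xlinked)) {
        start <- (i - 1L) * 1000000L + sample(1000:50000, 1L)
        len <- sample(5000:40000, 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = sprintf("XLG%02d", i), chrom = "chrX",
          start = start, end = start + len, inheritance = "XL",
          stringsAsFactors = FALSE)
      }
    }
    panel <- do.call(rbind, rows)
    rownames(panel) <- NULL
    panel
  })
}

#' Write / read a gene panel as BED-like TSV
#'
#' @param panel Panel data.frame from [gen_panel()].
#' @param path Output path.
#' @export
write_panel <- function(panel, path) write_tsv(panel, path)

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  panel <- read_tsv(path)
  stopifnot(all(c("gene", "chrom", "start", "end", "inheritance") %in%
    names(panel)))
  panel
}

# map variant rows to panel genes by interval containment
assign_gene <- function(variants, panel) {
  gene <- rep(NA_character_, nrow(variants))
  inheritance <- rep(NA_character_, nrow(variants))
  for (g in seq_len(nrow(panel))) {
    hit <- variants$chrom == panel$chrom[g] &
      variants$pos >= panel$start[g] & variants$pos <= panel$end[g]
    gene[hit] <- panel$gene[g]
    inheritance[hit] <- panel$inheritance[g]
  }
  variants$gene <- gene
  variants$inheritance <- inheritance
  variants
}
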