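# Synthetic phased cohort generator. Plants indicated-affected genotypes
# (hom / hemi / comphet) with exact ground truth; all other samples carry
# pathogenic-classified alleles only as isolated heterozygotes so they can
# never form a pathogenic genotype.

#' Generate a synthetic phased diploid cohort
#'
#' Samples are drawn from the requested ancestries with configurable sex
#' ratio. Each row of `affected_spec` plants one indicated-affected
#' individual: `hom` (alt|alt at one variant), `comphet` (two distinct
#' variants in the same gene on opposite haplotypes) or `hemi` (a male with
#' an alt allele in an X-linked gene, emitted as diploid alt|alt as phased
#' reference panels code male X). Background pathogenic-classified alleles
#' are sprinkled as isolated heterozygotes at `background_rate` per
#' sample-gene, at most one variant per sample per gene, never in males for
#' X-linked genes, and never in a sample planted in that gene.
#'
#' @param panel Panel from [gen_panel()].
#' @param ancestry_sizes Named integer vector, ancestry -> sample count.
#' @param affected_spec data.frame with columns `mechanism`
#'   ("hom"|"hemi"|"comphet") and `ancestry`; zero rows plants nobody.
#' @param seed Integer seed.
#' @param sex_ratio Probability a sample is male (default 0.5).
#' @param background_rate Per sample-gene heterozygous sprinkle rate.
#' @param background_vars_per_gene Pathogenic-classified background variants
#'   created per gene.
#' @return list with `variants` (chrom,pos,ref,alt,id), `gt` (variant x
#'   sample phased genotype matrix), `samples` (sample,sex,ancestry) and
#'   `ledger` (planted_affected + seed).
#' @export
gen_cohort <- function(panel, ancestry_sizes, affected_spec = NULL,
                       seed = 1L, sex_ratio = 0.5, background_rate = 0.01,
                       background_vars_per_gene = 2L) {
  stopifnot(is.numeric(ancestry_sizes), !is.null(names(ancestry_sizes)),
    all(ancestry_sizes >= 0))
  if (is.null(affected_spec)) {
    affected_spec <- data.frame(mechanism = character(0),
      ancestry = character(0), stringsAsFactors = FALSE)
  }
  stopifnot(all(affected_spec$mechanism %in% c("hom", "hemi", "comphet")),
    all(affected_spec$ancestry %in% names(ancestry_sizes)))
  ar_genes <- panel$gene[panel$inheritance == "AR"]
  xl_genes <- panel$gene[panel$inheritance == "XL"]
  if (any(affected_spec$mechanism == "hemi") && length(xl_genes) == 0L) {
    stop("hemi plant requested but the panel has no X-linked gene")
  }
  if (any(affected_spec$mechanism %in% c("hom", "comphet")) &&
      length(ar_genes) == 0L) {
    stop("hom/comphet plant requested but the panel has no autosomal gene")
  }

  with_seed(seed, {
    samples <- do.call(rbind, lapply(names(ancestry_sizes), function(a) {
      n <- ancestry_sizes[[a]]
      if (n == 0L) return(NULL)
      data.frame(sample = sprintf("%s%04d", a, seq_len(n)),
        sex = ifelse(stats::runif(n) < sex_ratio, "male", "female"),
        ancestry = a, stringsAsFactors = FALSE)
    }))
    if (is.null(samples) || nrow(samples) == 0L) stop("empty cohort")
    rownames(samples) <- NULL

    # variant scaffold: background variants per gene, then planted variants
    new_variant <- local({
      counter <- new.env()
      function(gene) {
        g <- panel[panel$gene == gene, ]
        k <- (counter[[gene]] <- (counter[[gene]] %||% 0L) + 1L)
        pos <- g$start + 10L * k   # spaced, inside the gene interval
        if (pos > g$end) stop("gene ", gene, " too small for variant count")
        refalt <- sample(c("A", "C", "G", "T"), 2L)
        data.frame(chrom = g$chrom, pos = pos, ref = refalt[1L],
          alt = refalt[2L], gene = gene, stringsAsFactors = FALSE)
      }
    })

    variants <- list()
    for (g in panel$gene) {
      for (i in seq_len(background_vars_per_gene)) {
        variants[[length(variants) + 1L]] <- new_variant(g)
      }
    }

    planted <- list()
    planted_gene_sample <- character(0)   # "sample@gene" exclusions
    used_samples <- character(0)
    ar_cycle <- 0L; xl_cycle <- 0L
    plant_rows <- list()
    n_spec <- nrow(affected_spec)
    for (i in seq_len(n_spec)) {
      mech <- affected_spec$mechanism[i]
      anc <- affected_spec$ancestry[i]
      pool <- samples$sample[samples$ancestry == anc &
        !(samples$sample %in% used_samples)]
      if (mech == "hemi") {
        pool <- intersect(pool,
          samples$sample[samples$sex == "male"])
        if (length(pool) == 0L) stop("no unused male sample in ", anc)
        xl_cycle <- xl_cycle + 1L
        gene <- xl_genes[((xl_cycle - 1L) %% length(xl_genes)) + 1L]
      } else {
        ar_cycle <- ar_cycle + 1L
        gene <- ar_genes[((ar_cycle - 1L) %% length(ar_genes)) + 1L]
      }
      if (length(pool) == 0L) stop("no unused sample in ancestry ", anc)
      smp <- pool[1L]
      used_samples <- c(used_samples, smp)
      nv <- if (mech == "comphet") 2L else 1L
      vs <- do.call(rbind, lapply(seq_len(nv), function(j) new_variant(gene)))
      variants[[length(variants) + 1L]] <- vs
      plant_rows[[i]] <- list(sample = smp, gene = gene, mechanism = mech,
        ancestry = anc, variants = vs)
      planted_gene_sample <- c(planted_gene_sample,
        paste0(smp, "@", gene))
    }

    variants <- do.call(rbind, variants)
    # sort by chromosome (panel order) then position
    chrom_order <- unique(panel$chrom)
    variants <- variants[order(match(variants$chrom, chrom_order),
      variants$pos), , drop = FALSE]
    rownames(variants) <- NULL
    variants$id <- key_id(variants$chrom, variants$pos,
      variants$ref, variants$alt)
    stopifnot(!anyDuplicated(variants$id))

    gt <- matrix("0|0", nrow = nrow(variants), ncol = nrow(samples),
      dimnames = list(variants$id, samples$sample))

    plant_df <- NULL
    if (n_spec > 0L) {
      plant_df <- do.call(rbind, lapply(plant_rows, function(p) {
        ids <- key_id(p$variants$chrom, p$variants$pos,
          p$variants$ref, p$variants$alt)
        if (p$mechanism == "comphet") {
          gt[ids[1L], p$sample] <<- "1|0"
          gt[ids[2L], p$sample] <<- "0|1"
        } else {
          gt[ids[1L], p$sample] <<- "1|1"
        }
        data.frame(sample = p$sample, gene = p$gene,
          mechanism = p$mechanism, ancestry = p$ancestry,
          variants = paste(ids, collapse = ","), stringsAsFactors = FALSE)
      }))
    } else {
      plant_df <- data.frame(sample = character(0), gene = character(0),
        mechanism = character(0), ancestry = character(0),
        variants = character(0), stringsAsFactors = FALSE)
    }

    # background sprinkle: isolated heterozygotes only
    vgene <- assign_gene(variants, panel)
    for (g in panel$gene) {
      vidx <- which(vgene$gene == g)
      if (length(vidx) == 0L) next
      is_xl <- panel$inheritance[panel$gene == g] == "XL"
      eligible <- samples$sample[!(paste0(samples$sample, "@", g) %in%
        planted_gene_sample)]
      if (is_xl) {
        eligible <- intersect(eligible,
          samples$sample[samples$sex == "female"])
      }
      hit <- eligible[stats::runif(length(eligible)) < background_rate]
      if (length(hit) == 0L) next
      pick <- vidx[sample.int(length(vidx), length(hit), replace = TRUE)]
      hap <- ifelse(stats::runif(length(hit)) < 0.5, "1|0", "0|1")
      for (j in seq_along(hit)) gt[pick[j], hit[j]] <- hap[j]
    }

    ledger <- list(planted_affected = plant_df,
      seeds = list(cohort = seed))
    list(variants = variants[, c("chrom", "pos", "ref", "alt", "id")],
      gt = gt, samples = samples, ledger = ledger)
  })
}

#' Write a cohort as a phased VCF 4.2 plus a sample sheet TSV
#'
#' @param cohort List from [gen_cohort()] (or [read_cohort()]).
#' @param vcf_path Output VCF path (plain text).
#' @param sample_sheet_path Output TSV path (sample, sex, ancestry).
#' @export
write_cohort <- function(cohort, vcf_path, sample_sheet_path = NULL) {
  v <- cohort$variants
  hdr <- c("##fileformat=VCFv4.2",
    "##source=classaudit-synthetic",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
      "INFO", "FORMAT", colnames(cohort$gt)), collapse = "\t"))
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
    apply(cohort$gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), vcf_path)
  if (!is.null(sample_sheet_path)) {
    write_tsv(cohort$samples, sample_sheet_path)
  }
  invisible(vcf_path)
}

#' Read a phased cohort VCF and sample sheet
#'
#' @param vcf_path Phased VCF with GT format field.
#' @param sample_sheet_path TSV with columns sample, sex, ancestry.
#' @return Cohort list (variants, gt, samples) as produced by
#'   [gen_cohort()].
#' @export
read_cohort <- function(vcf_path, sample_sheet_path) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  variants$id <- key_id(variants$chrom, variants$pos, variants$ref,
    variants$alt)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  rownames(gt) <- variants$id
  samples <- read_tsv(sample_sheet_path)
  stopifnot(all(c("sample", "sex", "ancestry") %in% names(samples)),
    identical(sort(colnames(gt)), sort(samples$sample)))
  gt <- gt[, samples$sample, drop = FALSE]
  list(variants = variants, gt = gt, samples = samples)
}
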