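# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check.

# --- minimal left-aligned representation ------------------------------
# Enumerate every (pos, ref, alt) with non-empty alleles that reproduces
# the same mutated sequence; the normalized form is the leftmost among
# those of minimal combined allele length.
oracle_normalize <- function(pos, ref, alt, context) {
  apply_var <- function(p, r, a) {
    stopifnot(substr(context, p, p + nchar(r) - 1L) == r)
    paste0(substr(context, 1L, p - 1L), a,
      substr(context, p + nchar(r), nchar(context)))
  }
  target <- apply_var(pos, ref, alt)
  best <- NULL
  n <- nchar(context)
  for (p in seq_len(n)) {
    for (lr in 1L:(n - p + 1L)) {
      r <- substr(context, p, p + lr - 1L)
      for (la in 1L:(lr + nchar(alt) + nchar(ref))) {
        # candidate alts: substrings of the target at the same spot
        a <- substr(target, p, p + la - 1L)
        if (nchar(a) < la) next
        if (r == a) next
        if (apply_var(p, r, a) != target) next
        cand <- list(pos = p, ref = r, alt = a, len = lr + la)
        if (is.null(best) || cand$len < best$len ||
            (cand$len == best$len && cand$pos < best$pos)) {
          best <- cand
        }
      }
    }
  }
  best
}

# --- exact 2x2 inference ----------------------------------------------
oracle_fisher_2x2 <- function(tab, alternative = "two_sided") {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2]) == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  a <- tab[1, 1]
  p_obs <- dhyper(a, r1, r2, c1)
  switch(alternative,
    two_sided = sum(probs[probs <= p_obs * (1 + 1e-7)]),
    greater = sum(probs[support >= a]),
    less = sum(probs[support <= a]))
}

# conditional-MLE odds ratio by direct numeric maximization of the
# noncentral hypergeometric likelihood
oracle_cmle_or <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  a <- tab[1, 1]
  if (a == min(support)) return(0)
  if (a == max(support)) return(Inf)
  logl <- function(logpsi) {
    w <- lchoose(r1, support) + lchoose(r2, c1 - support) +
      support * logpsi
    a * logpsi + lchoose(r1, a) + lchoose(r2, c1 - a) -
      max(w) - log(sum(exp(w - max(w))))
  }
  exp(stats::optimize(logl, c(-25, 25), maximum = TRUE,
    tol = 1e-10)$maximum)
}

# --- exact r x 2 p-value by full enumeration --------------------------
oracle_rxc_p <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  logdenom <- lgamma(n + 1) - sum(lgamma(rs + 1)) - sum(lgamma(cs + 1))
  logp <- function(a) {  # a: first column
    -(sum(lgamma(a + 1)) + sum(lgamma(rs - a + 1)) + logdenom)
  }
  p_obs <- logp(tab[, 1])
  tot <- 0
  enum <- function(i, remaining, a) {
    if (i > length(rs)) {
      if (remaining == 0) {
        lp <- logp(a)
        if (lp <= p_obs + 1e-7) tot <<- tot + exp(lp)
      }
      return(invisible(NULL))
    }
    for (ai in 0:min(rs[i], remaining)) {
      if (remaining - ai > sum(rs[-seq_len(i)])) next
      a[i] <- ai
      enum(i + 1L, remaining - ai, a)
    }
  }
  enum(1L, cs[1], numeric(length(rs)))
  tot
}

# --- brute-force affected scanner (O(samples x variants^2)) -----------
oracle_detect <- function(cohort, variant_set, panel) {
  hap <- function(g, k) {
    if (!grepl("|", g, fixed = TRUE)) return(NA_integer_)
    as.integer(strsplit(g, "|", fixed = TRUE)[[1]][k] != "0")
  }
  res <- list()
  for (s in cohort$samples$sample) {
    sex <- cohort$samples$sex[cohort$samples$sample == s]
    anc <- cohort$samples$ancestry[cohort$samples$sample == s]
    for (gi in seq_len(nrow(panel))) {
      gene <- panel$gene[gi]
      vids <- cohort$variants$id[
        cohort$variants$chrom == panel$chrom[gi] &
        cohort$variants$pos >= panel$start[gi] &
        cohort$variants$pos <= panel$end[gi] &
        cohort$variants$id %in% variant_set]
      if (length(vids) == 0L) next
      h1 <- vapply(vids, function(v) hap(cohort$gt[v, s], 1L), 0L)
      h2 <- vapply(vids, function(v) hap(cohort$gt[v, s], 2L), 0L)
      h1[is.na(h1)] <- 0L; h2[is.na(h2)] <- 0L
      mech <- NULL
      if (panel$inheritance[gi] == "XL" && sex == "male" &&
          any(h1 + h2 > 0)) {
        mech <- "hemi"
      } else if (any(h1 == 1 & h2 == 1)) {
        mech <- "hom"
      } else {
        found <- FALSE
        for (i in seq_along(vids)) {
          for (j in seq_along(vids)) {
            if (i != j && h1[i] == 1 && h2[j] == 1) found <- TRUE
          }
        }
        if (found) mech <- "comphet"
      }
      if (!is.null(mech)) {
        res[[length(res) + 1L]] <- data.frame(sample = s, gene = gene,
          mechanism = mech, ancestry = anc, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(sample = character(0), gene = character(0),
      mechanism = character(0), ancestry = character(0),
      stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}
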