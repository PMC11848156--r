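# small in-code fixtures shared across test files

# a sumstats object from minimal per-variant vectors; defaults give a
# clean 1-chromosome GWAS
toy_sumstats <- function(n = 5, chrom = "1", pos = NULL, beta = NULL,
                         se = NULL, pval = NULL, maf = NULL, info = NULL,
                         snp_id = NULL, a1 = "A", a2 = "G",
                         trait = "toy", n_total = 1000) {
  sumstats(data.frame(
    snp_id = snp_id %||% sprintf("rs%03d", seq_len(n)),
    chrom = rep_len(chrom, n),
    pos = pos %||% (1000L * seq_len(n)),
    allele_effect = rep_len(a1, n),
    allele_other = rep_len(a2, n),
    beta = beta %||% rep(0.1, n),
    se = se %||% rep(0.05, n),
    pval = pval %||% rep(0.5, n),
    maf = maf %||% rep(0.25, n),
    info = info %||% rep(0.99, n),
    stringsAsFactors = FALSE
  ), trait = trait, n_total = n_total)
}

# dosage_ref from a plain matrix with generated snp_ids
toy_dosage <- function(m, snp_ids = NULL) {
  m <- as.matrix(m)
  rownames(m) <- snp_ids %||% sprintf("rs%03d", seq_len(nrow(m)))
  dosage_ref(m)
}

# gene annotation data.frame (1-based inclusive coordinates)
toy_genes <- function(gene_id, chrom, start, end, strand = "+",
                      protein_coding = TRUE) {
  data.frame(gene_id = gene_id, chrom = as.character(chrom),
             start = as.integer(start), end = as.integer(end),
             strand = rep_len(strand, length(gene_id)),
             protein_coding = rep_len(protein_coding, length(gene_id)),
             stringsAsFactors = FALSE)
}

# harmonized-pairs table straight from w/b/s vectors
toy_pairs <- function(w, b, s, pexp = NULL, chrom = "1", pos = NULL) {
  n <- length(w)
  data.frame(
    snp_id = sprintf("rs%03d", seq_len(n)), chrom = rep_len(chrom, n),
    pos = pos %||% (1000L * seq_len(n)),
    allele_effect = "A", allele_other = "G",
    w = w, pval_exposure = pexp %||% rep(0.001, n), b = b, s = s,
    palindromic = FALSE, stringsAsFactors = FALSE
  )
}

# small architecture for fast simulation tests
small_arch <- function(...) {
  args <- list(
    n_snps = 600, n_genes = 100,
    ld_blocks = data.frame(size = 3, r = 0.9, n_blocks = 40),
    decoys = c(low_maf = 10, low_info = 10, apoe = 10, mhc = 10,
               intergenic = 5, multi_gene = 5)
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_architecture, args)
}

# the independent textbook WLS oracle: fit b ~ w with weights 1/s^2 and
# no intercept via lm — used to cross-check the closed-form IVW estimate
wls_oracle <- function(w, b, s) {
  fit <- stats::lm(b ~ w + 0, weights = 1 / s^2)
  list(alpha = unname(stats::coef(fit)[1L]),
       se = 1 / sqrt(sum(w^2 / s^2)))
}

# brute-force transcription of the greedy clumping definition, kept
# deliberately naive and separate from the production implementation
brute_force_clump <- function(ss, ld_ref, window_kb, r2_max) {
  v <- ss$variants
  retained <- character(0)
  repeat {
    if (!nrow(v)) break
    ord <- order(v$pval, v$chrom, v$pos)
    idx <- ord[1L]
    retained <- c(retained, v$snp_id[idx])
    drop <- rep(FALSE, nrow(v))
    for (j in seq_len(nrow(v))) {
      if (j == idx) next
      if (v$chrom[j] != v$chrom[idx]) next
      if (abs(v$pos[j] - v$pos[idx]) > window_kb * 1000) next
      if (compute_r2(v$snp_id[j], v$snp_id[idx], ld_ref) > r2_max) {
        drop[j] <- TRUE
      }
    }
    drop[idx] <- TRUE
    v <- v[!drop, , drop = FALSE]
  }
  retained
}

# exact upper-tail hypergeometric by direct combinatorial summation
hyper_tail_oracle <- function(x, white, black, drawn) {
  ks <- x:min(white, drawn)
  sum(exp(lchoose(white, ks) + lchoose(black, drawn - ks) -
            lchoose(white + black, drawn)))
}
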