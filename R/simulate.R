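#' Define a synthetic study architecture
#'
#' Fixes every structural choice of a simulated two-sample PRS study:
#' how many SNPs and genes, the 14 cell types and which one carries the
#' planted signal, the proportional effect of the exposure genetic score
#' on the outcome (`alpha_true`), the exposure heritability, the causal
#' fraction and the enrichment of causal effect mass in the target cell
#' type, the LD block structure, and the planted decoy variants
#' (low-MAF, low-INFO, APOE-region, MHC-region, intergenic, and
#' multi-gene SNPs) that exercise every QC and annotation rule.
#'
#' @param n_snps total SNPs (default 3000).
#' @param n_genes protein-coding genes (default 300; 10 additional
#'   non-coding genes are always placed).
#' @param cell_types cell type names (default: 14 brain/vascular types).
#' @param target_cell_type set carrying the planted enrichment
#'   (default "SMC").
#' @param alpha_true proportional effect of the standardized exposure
#'   genetic score on the outcome (default 0.3).
#' @param h2_exposure exposure heritability in \[0, 1) (default 0.5).
#' @param maf_range MAF range for regular SNPs (default c(0.05, 0.5)).
#' @param frac_causal fraction of regular SNPs with nonzero exposure
#'   effect (default 0.2).
#' @param enrichment ratio of mean squared causal effects, target cell
#'   type vs background (default 5).
#' @param outcome_concentration multiplier on the outcome coupling of
#'   target-cell-type SNPs: the outcome responds to the score
#'   sum(kappa_j x true_beta_j x dose_j) with kappa = this value for
#'   target-gene SNPs and 1 elsewhere, concentrating the proportional
#'   exposure-outcome effect in the designated cell type. `NULL`
#'   (default) uses `enrichment`, so an enrichment-1 architecture has a
#'   fully homogeneous coupling.
#' @param ld_blocks data.frame(size, r, n_blocks): LD blocks realized at
#'   dosage correlation r within consecutive same-chromosome SNPs;
#'   blocks are mutually independent (default 200 blocks of 3 SNPs at
#'   r = 0.9).
#' @param decoys named counts: `low_maf`, `low_info`, `apoe`, `mhc`,
#'   `intergenic`, `multi_gene`.
#' @param apoe_effect_mult effect-size multiplier for APOE-region decoy
#'   SNPs, all causal (default 5) — mirrors a single dominant locus.
#' @return Object of class `sim_architecture`.
#' @export
sim_architecture <- function(n_snps = 3000, n_genes = 300,
                             cell_types = default_cell_types(),
                             target_cell_type = "SMC",
                             alpha_true = 0.3, h2_exposure = 0.5,
                             maf_range = c(0.05, 0.5), frac_causal = 0.2,
                             enrichment = 5, outcome_concentration = NULL,
                             ld_blocks = data.frame(size = 3, r = 0.9,
                                                    n_blocks = 200),
                             decoys = c(low_maf = 30, low_info = 30,
                                        apoe = 30, mhc = 30,
                                        intergenic = 10, multi_gene = 10),
                             apoe_effect_mult = 5) {
  decoy_names <- c("low_maf", "low_info", "apoe", "mhc", "intergenic",
                   "multi_gene")
  full <- stats::setNames(rep(0L, length(decoy_names)), decoy_names)
  full[names(decoys)] <- decoys
  if (any(full < 0)) stop("decoy counts must be nonnegative")
  if (!target_cell_type %in% cell_types) {
    stop("target_cell_type must be one of cell_types")
  }
  if (frac_causal < 0 || frac_causal > 1) stop("frac_causal must lie in [0, 1]")
  if (h2_exposure < 0 || h2_exposure >= 1) stop("h2_exposure must lie in [0, 1)")
  n_regular <- n_snps - sum(full)
  if (n_regular < n_genes) stop("n_snps too small for the decoy counts")
  if (nrow(ld_blocks) && any(ld_blocks$size > n_regular)) {
    stop("infeasible LD block specification: block larger than SNP pool")
  }
  if (sum(ld_blocks$size * ld_blocks$n_blocks) > n_regular) {
    stop("infeasible LD block specification: blocks exceed the SNP pool")
  }
  structure(
    list(n_snps = n_snps, n_genes = n_genes, cell_types = cell_types,
         target_cell_type = target_cell_type, alpha_true = alpha_true,
         h2_exposure = h2_exposure, maf_range = maf_range,
         frac_causal = frac_causal, enrichment = enrichment,
         outcome_concentration = outcome_concentration %||% enrichment,
         ld_blocks = ld_blocks, decoys = full,
         apoe_effect_mult = apoe_effect_mult),
    class = "sim_architecture"
  )
}

#' The 14 default brain and vascular cell types
#' @return character vector of 14 cell type names.
#' @export
default_cell_types <- function() {
  c("SMC", "Pericyte", "Endothelial", "Ependymal", "Astrocyte",
    "Microglia", "Oligodendrocyte", "OPC", "ExcitNeuron", "InhibNeuron",
    "Fibroblast", "Tcell", "Macrophage", "ChoroidPlexus")
}

# genes in contiguous per-chromosome stretches with generous spacing so
# annotation windows of distinct genes never overlap, except deliberate
# overlapping pairs used for multi-gene decoy SNPs (last chromosome)
simulate_genes <- function(arch, seed) {
  set.seed(seed)
  chroms <- as.character(setdiff(1:22, c(6, 19)))
  n <- arch$n_genes
  per <- ceiling(n / length(chroms))
  chrom <- rep(chroms, each = per)[seq_len(n)]
  within <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  spacing <- 200000L
  start <- 1000000L + (within - 1L) * spacing
  len <- sample(10000:60000, n, replace = TRUE)
  genes <- data.frame(
    gene_id = sprintf("G%04d", seq_len(n)),
    chrom = chrom, start = start, end = start + len,
    strand = sample(c("+", "-"), n, replace = TRUE),
    protein_coding = TRUE, stringsAsFactors = FALSE
  )
  # overlap pairs for multi-gene decoys: shift the second gene of a pair
  # into the first gene's body
  n_multi <- arch$decoys[["multi_gene"]]
  if (n_multi > 0) {
    last_chrom <- genes$chrom == chrom[n]
    idx <- which(last_chrom)
    if (length(idx) < 2L * n_multi) {
      idx <- utils::tail(seq_len(n), 2L * n_multi)
    }
    for (k in seq_len(n_multi)) {
      a <- idx[2L * k - 1L]
      b <- idx[2L * k]
      glen <- genes$end[b] - genes$start[b]
      genes$start[b] <- genes$end[a] - 5000L
      genes$end[b] <- genes$start[b] + glen
    }
  }
  # non-coding genes: eligible positions for unmapped decoy SNPs
  nc <- data.frame(
    gene_id = sprintf("NC%02d", 1:10),
    chrom = rep(chroms[1:5], each = 2),
    start = 90000000L + rep(c(0L, 300000L), 5),
    end = 90000000L + rep(c(0L, 300000L), 5) + 20000L,
    strand = "+", protein_coding = FALSE, stringsAsFactors = FALSE
  )
  genes <- rbind(genes, nc)
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  genes
}

# random near-equal partition of the protein-coding genes into cell types
simulate_cell_sets <- function(arch, genes, seed) {
  set.seed(seed)
  ids <- sample(genes$gene_id[genes$protein_coding])
  grp <- rep_len(arch$cell_types, length(ids))
  sets <- split(ids, grp)[arch$cell_types]
  structure(sets, class = "cell_type_sets")
}

# place every SNP, draw MAF/INFO/alleles, assign LD blocks
simulate_variant_meta <- function(arch, genes, seed) {
  set.seed(seed)
  d <- arch$decoys
  pc <- genes[genes$protein_coding, , drop = FALSE]
  n_regular <- arch$n_snps - sum(d)

  place_in_genes <- function(k) {
    gi <- sample(nrow(pc), k, replace = TRUE)
    pos <- pc$start[gi] +
      floor(stats::runif(k) * (pc$end[gi] - pc$start[gi] + 1L))
    data.frame(chrom = pc$chrom[gi], pos = as.integer(pos),
               gene_id = pc$gene_id[gi], stringsAsFactors = FALSE)
  }
  with_class <- function(df, cls) {
    df$class <- rep(cls, nrow(df))
    df
  }
  region_snps <- function(k, chrom, lo, hi, cls) {
    data.frame(chrom = rep(chrom, k), pos = sort(sample(lo:hi, k)),
               gene_id = rep(NA_character_, k), class = rep(cls, k),
               stringsAsFactors = FALSE)
  }
  reg <- with_class(place_in_genes(n_regular), "regular")
  lowm <- with_class(place_in_genes(d[["low_maf"]]), "low_maf")
  lowi <- with_class(place_in_genes(d[["low_info"]]), "low_info")
  apoe <- region_snps(d[["apoe"]], "19", 44500000L, 46000000L, "apoe")
  mhc <- region_snps(d[["mhc"]], "6", 26000000L, 34000000L, "mhc")
  nc <- genes[!genes$protein_coding, , drop = FALSE]
  n_ig <- d[["intergenic"]]
  ig <- if (n_ig > 0) {
    gi <- rep_len(seq_len(nrow(nc)), n_ig)
    data.frame(chrom = nc$chrom[gi],
               pos = as.integer(nc$start[gi] + seq_len(n_ig) * 37L),
               gene_id = NA_character_, class = "intergenic",
               stringsAsFactors = FALSE)
  } else NULL
  # multi-gene decoys sit in the overlap of the deliberately overlapping
  # gene pairs
  n_mg <- d[["multi_gene"]]
  mg <- NULL
  if (n_mg > 0) {
    ov <- overlapping_pairs(genes)
    gi <- rep_len(seq_len(nrow(ov)), n_mg)
    mg <- data.frame(chrom = ov$chrom[gi],
                     pos = as.integer(ov$ov_start[gi] +
                                        seq_len(n_mg) %% pmax(1L, ov$ov_len[gi])),
                     gene_id = ov$gene_a[gi], class = "multi_gene",
                     stringsAsFactors = FALSE)
  }
  meta <- rbind(reg, lowm, lowi, apoe, mhc, ig, mg)

  n <- nrow(meta)
  meta$maf <- stats::runif(n, arch$maf_range[1L], arch$maf_range[2L])
  meta$maf[meta$class == "low_maf"] <- stats::runif(sum(meta$class == "low_maf"),
                                                    0.001, 0.009)
  meta$info <- stats::runif(n, 0.9, 1.0)
  meta$info[meta$class == "low_info"] <- stats::runif(sum(meta$class == "low_info"),
                                                      0.3, 0.89)
  al <- t(vapply(seq_len(n), function(i) sample(c("A", "C", "G", "T"), 2L),
                 character(2L)))
  meta$allele_effect <- al[, 1L]
  meta$allele_other <- al[, 2L]

  meta <- meta[order(meta$chrom, meta$pos), , drop = FALSE]
  dup <- duplicated(paste(meta$chrom, meta$pos))
  while (any(dup)) {  # nudge positional collisions
    meta$pos[dup] <- meta$pos[dup] + 1L
    meta <- meta[order(meta$chrom, meta$pos), , drop = FALSE]
    dup <- duplicated(paste(meta$chrom, meta$pos))
  }
  meta$snp_id <- sprintf("rs%06d", seq_len(n))
  rownames(meta) <- NULL

  # LD blocks: runs of consecutive regular same-chromosome SNPs; one MAF
  # per block (tight LD implies similar allele frequency)
  meta$block <- NA_integer_
  meta$block_r <- NA_real_
  bid <- 0L
  reg_idx <- which(meta$class == "regular")
  if (nrow(arch$ld_blocks)) {
    total_blocks <- sum(arch$ld_blocks$n_blocks)
    stride <- max(1L, floor(length(reg_idx) / total_blocks))
    cursor <- 1L
    for (spec in seq_len(nrow(arch$ld_blocks))) {
      size <- arch$ld_blocks$size[spec]
      r <- arch$ld_blocks$r[spec]
      made <- 0L
      while (made < arch$ld_blocks$n_blocks[spec] &&
             cursor + size - 1L <= length(reg_idx)) {
        members <- reg_idx[cursor:(cursor + size - 1L)]
        if (length(unique(meta$chrom[members])) == 1L &&
            all(is.na(meta$block[members]))) {
          bid <- bid + 1L
          meta$block[members] <- bid
          meta$block_r[members] <- r
          meta$maf[members] <- meta$maf[members[1L]]
          made <- made + 1L
          cursor <- cursor + max(size, stride)
        } else {
          cursor <- cursor + 1L
        }
      }
    }
  }
  meta[, c("snp_id", "chrom", "pos", "allele_effect", "allele_other",
           "maf", "info", "gene_id", "class", "block", "block_r")]
}

overlapping_pairs <- function(genes) {
  pc <- genes[genes$protein_coding, , drop = FALSE]
  pc <- pc[order(pc$chrom, pc$start), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(pc) - 1L)) {
    j <- i + 1L
    if (pc$chrom[i] == pc$chrom[j] && pc$start[j] <= pc$end[i]) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = pc$chrom[i], gene_a = pc$gene_id[i], gene_b = pc$gene_id[j],
        ov_start = pc$start[j], ov_len = pc$end[i] - pc$start[j],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Simulate genotype dosages for a cohort
#'
#' Hardy-Weinberg genotypes (two independent Bernoulli haplotypes) at
#' each SNP's MAF. LD blocks use a shared-template haplotype-copying
#' scheme: within a block each haplotype copies a common template allele
#' with probability sqrt(r) and otherwise draws independently, which
#' makes the expected dosage correlation of any two block members
#' exactly r. SNPs in distinct blocks (and unblocked SNPs) are
#' independent.
#'
#' @param meta variant metadata from [simulate_variant_meta] (columns
#'   `snp_id`, `maf`, `block`, `block_r`).
#' @param n_ind number of individuals (>= 50).
#' @param seed integer seed.
#' @return numeric matrix n_ind x n_snps of dosages in \{0, 1, 2\},
#'   column names = snp_id.
#' @export
simulate_genotypes <- function(meta, n_ind, seed) {
  if (n_ind < 50) stop("n_ind must be at least 50")
  set.seed(seed)
  block <- meta$block
  if (is.null(block)) block <- rep(NA_integer_, nrow(meta))
  block_r <- meta$block_r
  if (is.null(block_r)) block_r <- rep(NA_real_, nrow(meta))
  X <- sim_dosages_cpp(as.integer(n_ind), as.numeric(meta$maf),
                       as.integer(block), as.numeric(block_r))
  colnames(X) <- meta$snp_id
  X
}

#' Plant the true genetic architecture
#'
#' Draws the per-SNP true exposure effects: a `frac_causal` fraction of
#' regular SNPs receive normal effects whose variance is multiplied by
#' `enrichment` when the SNP's gene belongs to the target cell type's
#' set; APOE-region decoy SNPs all receive large effects
#' (`apoe_effect_mult` x the background scale). Everything is recorded
#' before any noise enters downstream stages.
#'
#' @param arch a [sim_architecture].
#' @param meta variant metadata.
#' @param cell_sets named list of gene sets covering the protein-coding
#'   genes.
#' @param seed integer seed.
#' @return List of class `sim_truth`: `snp` (per-SNP data.frame with
#'   `true_beta`, `causal`, `gene_id`, `cell_type`, `class`),
#'   `alpha_true`, `h2_exposure`, `target_cell_type`, `causal_ids`.
#' @export
build_architecture <- function(arch, meta, cell_sets, seed) {
  covered <- unique(unlist(cell_sets))
  mapped_genes <- unique(meta$gene_id[meta$class == "regular"])
  if (!all(mapped_genes %in% covered)) {
    stop("cell-type sets do not cover the simulated genes")
  }
  set.seed(seed)
  gene2type <- rep(names(cell_sets), lengths(cell_sets))
  names(gene2type) <- unlist(cell_sets)
  snp <- meta[, c("snp_id", "gene_id", "class")]
  snp$cell_type <- unname(gene2type[snp$gene_id])
  snp$causal <- FALSE
  snp$true_beta <- 0
  is_target <- !is.na(snp$cell_type) & snp$cell_type == arch$target_cell_type
  snp$outcome_mult <- ifelse(is_target, arch$outcome_concentration, 1)

  reg <- which(snp$class == "regular")
  causal <- reg[stats::runif(length(reg)) < arch$frac_causal]
  snp$causal[causal] <- TRUE
  sd_mult <- ifelse(!is.na(snp$cell_type[causal]) &
                      snp$cell_type[causal] == arch$target_cell_type,
                    sqrt(arch$enrichment), 1)
  snp$true_beta[causal] <- stats::rnorm(length(causal)) * sd_mult

  apoe <- which(snp$class == "apoe")
  if (length(apoe)) {
    snp$causal[apoe] <- TRUE
    snp$true_beta[apoe] <- stats::rnorm(length(apoe), sd = arch$apoe_effect_mult)
  }
  structure(
    list(snp = snp, alpha_true = arch$alpha_true,
         h2_exposure = arch$h2_exposure,
         target_cell_type = arch$target_cell_type,
         enrichment = arch$enrichment,
         outcome_concentration = arch$outcome_concentration,
         causal_ids = snp$snp_id[snp$causal]),
    class = "sim_truth"
  )
}

#' Simulate exposure and outcome phenotypes for a cohort
#'
#' The exposure genetic score is G = sum(true_beta x dose),
#' standardized; the exposure liability adds environmental noise scaled
#' to `h2_exposure`. The outcome responds proportionally (`alpha_true`)
#' to the outcome-coupled score sum(kappa x true_beta x dose), where
#' kappa concentrates the effect in the target cell type
#' (`outcome_concentration`; kappa = 1 everywhere reduces this to
#' `alpha_true` x standardized G). The outcome is standardized to unit
#' sample variance.
#'
#' @param truth a [build_architecture] result.
#' @param X dosage matrix from [simulate_genotypes] (same architecture).
#' @param seed integer seed.
#' @return List: `G` (standardized exposure genetic score), `G_out`
#'   (standardized outcome-coupled score), `exposure`, `outcome`
#'   (numeric vectors of length n_ind).
#' @export
simulate_phenotypes <- function(truth, X, seed) {
  if (truth$h2_exposure < 0 || truth$h2_exposure >= 1) {
    stop("h2_exposure must lie in [0, 1)")
  }
  set.seed(seed)
  n <- nrow(X)
  idx <- match(colnames(X), truth$snp$snp_id)
  beta <- truth$snp$true_beta[idx]
  beta[is.na(beta)] <- 0
  kappa <- truth$snp$outcome_mult[idx]
  kappa[is.na(kappa)] <- 1
  std0 <- function(v) if (stats::sd(v) > 0) as.vector(scale(v)) else rep(0, n)
  Gs <- std0(as.vector(X %*% beta))
  Gout <- std0(as.vector(X %*% (beta * kappa)))
  h2 <- truth$h2_exposure
  exposure <- sqrt(h2) * Gs + sqrt(1 - h2) * stats::rnorm(n)
  a <- truth$alpha_true
  resid_sd <- sqrt(max(0, 1 - a^2))
  y <- a * Gout + resid_sd * stats::rnorm(n)
  if (stats::sd(y) > 0) y <- as.vector(scale(y))
  list(G = Gs, G_out = Gout, exposure = exposure, outcome = y)
}

#' Single-SNP GWAS on a simulated cohort
#'
#' Regresses the phenotype marginally on each SNP's dose (with
#' intercept): beta = cov(dose, y) / var(dose), SE from the residual
#' variance, p from the t statistic. MAF is computed from the dosages
#' (folded); INFO is the planted per-variant metadata. Monomorphic SNPs
#' have no defined beta and are dropped with a log entry.
#'
#' @param X dosage matrix (individuals x SNPs, named columns).
#' @param y phenotype vector (length nrow(X), or length(rows) when
#'   `rows` is given).
#' @param meta variant metadata (alleles, INFO) aligned by snp_id.
#' @param trait trait label.
#' @param rows optional row indices: run the GWAS on this sub-cohort
#'   without copying the dosage matrix.
#' @return A [sumstats] object.
#' @export
run_gwas <- function(X, y, meta, trait = "trait", rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(X))
  n <- length(rows)
  stopifnot(length(y) == n, n > 2)
  yc <- y - mean(y)
  cs <- col_gwas_stats_cpp(X, yc, as.integer(rows))
  cm <- cs[1L, ]
  css <- cs[2L, ]
  sxy <- cs[3L, ]
  snp_ids <- colnames(X)
  mono <- css <= 1e-12
  if (any(mono)) {
    message(sum(mono), " monomorphic SNP(s) dropped from GWAS")
    cm <- cm[!mono]
    css <- css[!mono]
    sxy <- sxy[!mono]
    snp_ids <- snp_ids[!mono]
  }
  beta <- sxy / css
  syy <- sum(yc^2)
  sse <- pmax(0, syy - beta * sxy)
  sigma2 <- sse / (n - 2)
  se <- pmax(sqrt(sigma2 / css), 1e-12)
  tstat <- beta / se
  pval <- pmin(pmax(2 * stats::pt(-abs(tstat), df = n - 2), 1e-300), 1)
  m <- meta[match(snp_ids, meta$snp_id), , drop = FALSE]
  maf <- pmin(cm / 2, 1 - cm / 2)
  sumstats(
    data.frame(snp_id = snp_ids, chrom = m$chrom, pos = m$pos,
               allele_effect = m$allele_effect, allele_other = m$allele_other,
               beta = beta, se = se, pval = pval, maf = maf, info = m$info,
               n = n, stringsAsFactors = FALSE),
    trait = trait, n_total = n
  )
}

#' Split a cohort and run discovery / replication / combined GWAS
#'
#' Simple random split into disjoint discovery and replication halves;
#' the combined GWAS uses everyone. Either half falling below 50
#' individuals is a configuration error.
#'
#' @param X dosage matrix.
#' @param y phenotype.
#' @param meta variant metadata.
#' @param frac_discovery fraction assigned to discovery (default 2/3).
#' @param seed integer seed for the split.
#' @param trait trait label prefix.
#' @return List of three [sumstats]: `discovery`, `replication`,
#'   `combined`, plus `idx_discovery`.
#' @export
split_sample <- function(X, y, meta, frac_discovery = 2 / 3, seed = 1L,
                         trait = "outcome") {
  if (frac_discovery <= 0 || frac_discovery >= 1) {
    stop("frac_discovery must lie in (0, 1)")
  }
  n <- nrow(X)
  n_disc <- round(frac_discovery * n)
  if (n_disc < 50 || n - n_disc < 50) {
    stop("split leaves fewer than 50 individuals in one half")
  }
  set.seed(seed)
  idx <- sample.int(n, n_disc)
  rest <- setdiff(seq_len(n), idx)
  list(
    discovery = run_gwas(X, y[idx], meta, paste0(trait, "_discovery"),
                         rows = idx),
    replication = run_gwas(X, y[rest], meta, paste0(trait, "_replication"),
                           rows = rest),
    combined = run_gwas(X, y, meta, paste0(trait, "_combined")),
    idx_discovery = idx
  )
}

#' Simulate a gene x cell-type mean-expression table
#'
#' Count-scale expression with Poisson noise around a base mean, where
#' each gene is over-expressed (`fold` x) in its assigned cell type —
#' the input [score_marker_enrichment] consumes to recover the marker
#' sets.
#'
#' @param cell_sets named list of gene sets (the planted markers).
#' @param seed integer seed.
#' @param base_mean baseline expression (default 50).
#' @param fold over-expression fold change in the own type (default 8).
#' @return numeric gene x cell-type matrix.
#' @export
simulate_expression <- function(cell_sets, seed, base_mean = 50, fold = 8) {
  set.seed(seed)
  genes <- unlist(cell_sets, use.names = FALSE)
  types <- names(cell_sets)
  gene2type <- rep(types, lengths(cell_sets))
  lambda <- matrix(base_mean, length(genes), length(types),
                   dimnames = list(genes, types))
  lambda[cbind(seq_along(genes), match(gene2type, types))] <- base_mean * fold
  matrix(stats::rpois(length(lambda), lambda), nrow(lambda), ncol(lambda),
         dimnames = dimnames(lambda))
}

#' Simulate a complete two-sample PRS study
#'
#' Generates everything the pipeline consumes, with ground truth: gene
#' annotation, cell-type sets, variant metadata with planted decoys, an
#' exposure cohort (its GWAS supplies the score weights), an independent
#' outcome cohort (split into discovery/replication, plus the combined
#' GWAS), and a small LD reference panel. All randomness flows from
#' `seed` through named per-stage substreams.
#'
#' @param arch a [sim_architecture].
#' @param n_exposure exposure-cohort size (default 20000).
#' @param n_outcome outcome-cohort size (default 20000).
#' @param n_ld_ref LD reference panel size (default 500).
#' @param frac_discovery discovery fraction of the outcome cohort.
#' @param seed master seed.
#' @return List of class `sim_study`: `genes`, `cell_sets`, `meta`,
#'   `truth`, `exposure_stats`, `outcome` (list discovery / replication
#'   / combined), `ld_ref`, `arch`, `seed`.
#' @export
simulate_study <- function(arch = sim_architecture(), n_exposure = 20000,
                           n_outcome = 20000, n_ld_ref = 500,
                           frac_discovery = 2 / 3, seed = 1L) {
  genes <- simulate_genes(arch, rng_substream(seed, "genes"))
  cell_sets <- simulate_cell_sets(arch, genes, rng_substream(seed, "cell_sets"))
  meta <- simulate_variant_meta(arch, genes, rng_substream(seed, "variants"))
  truth <- build_architecture(arch, meta, cell_sets,
                              rng_substream(seed, "effects"))

  Xe <- simulate_genotypes(meta, n_exposure, rng_substream(seed, "geno_exposure"))
  phe <- simulate_phenotypes(truth, Xe, rng_substream(seed, "pheno_exposure"))
  exposure_stats <- run_gwas(Xe, phe$exposure, meta, "exposure")
  rm(Xe)

  Xo <- simulate_genotypes(meta, n_outcome, rng_substream(seed, "geno_outcome"))
  pho <- simulate_phenotypes(truth, Xo, rng_substream(seed, "pheno_outcome"))
  outcome <- split_sample(Xo, pho$outcome, meta, frac_discovery,
                          rng_substream(seed, "split"), trait = "outcome")
  rm(Xo)

  Xr <- simulate_genotypes(meta, n_ld_ref, rng_substream(seed, "geno_ldref"))
  Xr <- t(Xr)
  colnames(Xr) <- sprintf("I%04d", seq_len(n_ld_ref))
  ld_ref <- dosage_ref(Xr, variants = meta)
  rm(Xr)

  structure(
    list(genes = genes, cell_sets = cell_sets, meta = meta, truth = truth,
         exposure_stats = exposure_stats,
         outcome = outcome[c("discovery", "replication", "combined")],
         ld_ref = ld_ref, arch = arch, seed = seed),
    class = "sim_study"
  )
}

#' Write a simulated study to disk in the interchange formats
#'
#' Emits the exposure and outcome summary-statistic TSVs, the gene
#' annotation BED, the cell-set GMT, the LD-reference dosage TSV, and a
#' ground-truth JSON.
#'
#' @param study a [simulate_study] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sumstats(study$exposure_stats, file.path(dir, "exposure_gwas.tsv"))
  for (nm in names(study$outcome)) {
    write_sumstats(study$outcome[[nm]],
                   file.path(dir, paste0("outcome_", nm, ".tsv")))
  }
  write_gene_annotation(study$genes, file.path(dir, "genes.bed"))
  write_gene_sets(study$cell_sets, file.path(dir, "cell_sets.gmt"))
  write_dosage_matrix(study$ld_ref, file.path(dir, "ld_reference.tsv"))
  truth <- list(
    alpha_true = study$truth$alpha_true,
    h2_exposure = study$truth$h2_exposure,
    target_cell_type = study$truth$target_cell_type,
    enrichment = study$truth$enrichment,
    causal_ids = study$truth$causal_ids,
    seed = study$seed
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
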