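no_ld <- data.frame(size = numeric(0), r = numeric(0), n_blocks = numeric(0))

test_that("architecture validation catches infeasible specifications", {
  expect_error(sim_architecture(target_cell_type = "nope"), "target_cell_type")
  expect_error(sim_architecture(h2_exposure = 1), "h2_exposure")
  expect_error(sim_architecture(n_snps = 150, n_genes = 10,
                                ld_blocks = data.frame(size = 500, r = 0.9,
                                                       n_blocks = 1)),
               "infeasible")
  expect_error(sim_architecture(decoys = c(low_maf = -1)), "nonnegative")
  expect_error(simulate_genotypes(data.frame(snp_id = "a", maf = 0.1,
                                             block = NA, block_r = NA),
                                  n_ind = 10, seed = 1), "at least 50")
})

test_that("genotypes are Hardy-Weinberg at the drawn MAF with block LD", {
  meta <- data.frame(snp_id = c("a", "b", "c", "d"),
                     maf = c(0.5, 0.5, 0.1, 0.1),
                     block = c(1L, 1L, NA, NA), block_r = c(0.95, 0.95, NA, NA))
  X <- simulate_genotypes(meta, 10000, seed = 5)
  # MAF 0.5 -> mean dose 1 within binomial error
  expect_lt(abs(mean(X[, "a"]) - 1), 0.03)
  expect_lt(abs(mean(X[, "c"]) - 0.2), 0.02)
  # within-block pair at r = 0.95: strong dosage correlation
  expect_gt(cor(X[, "a"], X[, "b"])^2, 0.8)
  # cross-block pair independent
  expect_lt(cor(X[, "a"], X[, "c"])^2, 0.01)

  # no blocks: pairwise r^2 small across 100 random pairs
  set.seed(6)
  meta2 <- data.frame(snp_id = sprintf("s%03d", 1:60),
                      maf = runif(60, 0.05, 0.5),
                      block = NA_integer_, block_r = NA_real_)
  X2 <- simulate_genotypes(meta2, 5000, seed = 6)
  r2 <- replicate(100, {
    ij <- sample.int(60, 2)
    cor(X2[, ij[1]], X2[, ij[2]])^2
  })
  expect_lt(mean(r2), 0.01)

  # determinism
  expect_identical(simulate_genotypes(meta, 100, seed = 3),
                   simulate_genotypes(meta, 100, seed = 3))
})

test_that("planted architectures realize the configured enrichment ratio", {
  # null architecture: no causal effects at all
  arch0 <- small_arch(frac_causal = 0)
  genes <- ctprs:::simulate_genes(arch0, 1)
  sets <- ctprs:::simulate_cell_sets(arch0, genes, 2)
  meta <- ctprs:::simulate_variant_meta(arch0, genes, 3)
  truth0 <- build_architecture(arch0, meta, sets, 4)
  expect_true(all(truth0$snp$true_beta[truth0$snp$class == "regular"] == 0))

  ratio_of <- function(truth, target) {
    s <- truth$snp[truth$snp$causal & truth$snp$class == "regular", ]
    tgt <- s$cell_type == target
    mean(s$true_beta[tgt]^2) / mean(s$true_beta[!tgt]^2)
  }
  # enrichment 1: target mean squared effect matches background
  arch1 <- sim_architecture(enrichment = 1)
  genes1 <- ctprs:::simulate_genes(arch1, 11)
  sets1 <- ctprs:::simulate_cell_sets(arch1, genes1, 12)
  meta1 <- ctprs:::simulate_variant_meta(arch1, genes1, 13)
  truth1 <- build_architecture(arch1, meta1, sets1, 14)
  expect_lt(abs(log(ratio_of(truth1, "SMC"))), log(2.2))

  # enrichment 5 at frac_causal 0.2, n_snps 3000: realized ratio in [3, 7]
  arch5 <- sim_architecture(enrichment = 5, frac_causal = 0.2)
  truth5 <- build_architecture(arch5, meta1, sets1, 15)
  r <- ratio_of(truth5, "SMC")
  expect_gt(r, 3); expect_lt(r, 7)

  # APOE decoys carry large planted effects
  expect_true(all(truth5$snp$causal[truth5$snp$class == "apoe"]))
  # sets not covering the genes is a config error
  expect_error(build_architecture(arch5, meta1, sets1[1:3], 16), "cover")
})

test_that("phenotypes follow the planted proportional model", {
  arch <- small_arch(alpha_true = 0, enrichment = 1, ld_blocks = no_ld)
  genes <- ctprs:::simulate_genes(arch, 1)
  sets <- ctprs:::simulate_cell_sets(arch, genes, 2)
  meta <- ctprs:::simulate_variant_meta(arch, genes, 3)
  truth <- build_architecture(arch, meta, sets, 4)
  X <- simulate_genotypes(meta, 4000, seed = 5)

  # alpha_true = 0: correlation of score and outcome is pure noise
  ph0 <- simulate_phenotypes(truth, X, seed = 6)
  expect_lt(abs(cor(ph0$G, ph0$outcome)), 2 / sqrt(4000))

  # deterministic limit: alpha_true = 1 makes the outcome a monotone
  # function of the score
  truth1 <- truth; truth1$alpha_true <- 1
  ph1 <- simulate_phenotypes(truth1, X, seed = 7)
  expect_equal(cor(ph1$G, ph1$outcome, method = "spearman"), 1)

  # closed-form OLS oracle: slope of outcome on standardized score
  # recovers alpha_true
  truth01 <- truth; truth01$alpha_true <- 0.1
  Xbig <- simulate_genotypes(meta, 20000, seed = 8)
  ph <- simulate_phenotypes(truth01, Xbig, seed = 9)
  slope <- cov(ph$outcome, ph$G) / var(ph$G)
  expect_lt(abs(slope - 0.1), 0.02)

  bad <- truth; bad$h2_exposure <- 1.5
  expect_error(simulate_phenotypes(bad, X, 1), "h2_exposure")
})

test_that("the marginal GWAS matches textbook OLS and calibrates its p-values", {
  # perfect-fit toy: beta 1 with (floored) zero residual
  meta1 <- data.frame(snp_id = "t1", chrom = "1", pos = 100L,
                      allele_effect = "A", allele_other = "G", info = 0.99,
                      stringsAsFactors = FALSE)
  X1 <- matrix(c(0, 1, 2, 1), 4, 1, dimnames = list(NULL, "t1"))
  ss1 <- run_gwas(X1, c(0, 1, 2, 1), meta1)
  expect_equal(ss1$variants$beta, 1)
  expect_lt(ss1$variants$se, 1e-10)

  # beta equals lm() slope on 20 random SNPs
  set.seed(16)
  arch <- small_arch(ld_blocks = no_ld)
  genes <- ctprs:::simulate_genes(arch, 1)
  meta <- ctprs:::simulate_variant_meta(arch, genes, 3)
  X <- simulate_genotypes(meta, 500, seed = 4)
  y <- rnorm(500)
  ss <- suppressMessages(run_gwas(X, y, meta))
  for (s in sample(ss$variants$snp_id, 20)) {
    fit <- summary(lm(y ~ X[, s]))$coefficients
    expect_equal(ss$variants$beta[ss$variants$snp_id == s],
                 fit[2, "Estimate"], tolerance = 1e-10)
    expect_equal(ss$variants$se[ss$variants$snp_id == s],
                 fit[2, "Std. Error"], tolerance = 1e-10)
    expect_equal(ss$variants$pval[ss$variants$snp_id == s],
                 fit[2, "Pr(>|t|)"], tolerance = 1e-9)
  }

  # type-I calibration: independent phenotype gives ~5% of p < 0.05
  frac <- mean(ss$variants$pval < 0.05)
  m <- n_variants(ss)
  ci <- qbinom(c(0.005, 0.995), m, 0.05) / m
  expect_gte(frac, ci[1]); expect_lte(frac, ci[2])

  # monomorphic SNPs are dropped with a message
  Xm <- cbind(X[, 1:3], mono = 0)
  colnames(Xm)[1:3] <- colnames(X)[1:3]
  meta_m <- rbind(meta[1:3, c("snp_id", "chrom", "pos", "allele_effect",
                              "allele_other", "info")],
                  data.frame(snp_id = "mono", chrom = "9", pos = 1L,
                             allele_effect = "A", allele_other = "C",
                             info = 0.95))
  meta_m$maf <- 0.2; meta_m$block <- NA; meta_m$block_r <- NA
  expect_message(ssm <- run_gwas(Xm, y, meta_m), "monomorphic")
  expect_false("mono" %in% ssm$variants$snp_id)
})

test_that("sample splitting is exact, deterministic, and preserves signal", {
  arch <- small_arch(alpha_true = 0.3)
  genes <- ctprs:::simulate_genes(arch, 1)
  sets <- ctprs:::simulate_cell_sets(arch, genes, 2)
  meta <- ctprs:::simulate_variant_meta(arch, genes, 3)
  truth <- build_architecture(arch, meta, sets, 4)
  X <- simulate_genotypes(meta, 3000, seed = 5)
  ph <- simulate_phenotypes(truth, X, seed = 6)

  sp <- suppressMessages(split_sample(X, ph$outcome, meta, 2 / 3, seed = 7))
  expect_equal(sp$discovery$n_total, 2000L)
  expect_equal(sp$replication$n_total, 1000L)
  expect_equal(sp$combined$n_total, 3000L)
  sp2 <- suppressMessages(split_sample(X, ph$outcome, meta, 2 / 3, seed = 7))
  expect_identical(sp$idx_discovery, sp2$idx_discovery)
  expect_identical(sp$discovery$variants, sp2$discovery$variants)
  expect_error(split_sample(X[1:60, ], ph$outcome[1:60], meta, 0.5, 1),
               "fewer than 50")

  # discovery and replication betas correlate positively at causal SNPs
  Xb <- simulate_genotypes(meta, 10000, seed = 8)
  phb <- simulate_phenotypes(truth, Xb, seed = 9)
  spb <- suppressMessages(split_sample(Xb, phb$outcome, meta, 2 / 3, seed = 10))
  causal <- intersect(truth$causal_ids, spb$discovery$variants$snp_id)
  bd <- spb$discovery$variants$beta[match(causal, spb$discovery$variants$snp_id)]
  br <- spb$replication$variants$beta[match(causal, spb$replication$variants$snp_id)]
  expect_gt(cor(bd, br), 0)
  expect_lt(cor.test(bd, br)$p.value, 0.05)
})

test_that("a full simulated study is internally consistent", {
  arch <- small_arch()
  study <- suppressMessages(
    simulate_study(arch, n_exposure = 1000, n_outcome = 1000,
                   n_ld_ref = 200, seed = 31))
  expect_s3_class(study$exposure_stats, "sumstats")
  expect_equal(length(study$cell_sets), 14L)
  expect_equal(study$truth$target_cell_type, "SMC")
  # decoy classes present in the planted metadata
  expect_equal(as.integer(table(study$meta$class)[c("apoe", "mhc")]),
               c(10L, 10L))
  # the LD reference covers the variant universe
  expect_setequal(rownames(study$ld_ref$dosages), study$meta$snp_id)
  # same seed reproduces the study exactly
  study2 <- suppressMessages(
    simulate_study(arch, 1000, 1000, 200, seed = 31))
  expect_identical(study$exposure_stats$variants, study2$exposure_stats$variants)
  expect_identical(study$truth$snp, study2$truth$snp)
})

test_that("study files round-trip through the interchange formats", {
  arch <- small_arch()
  study <- suppressMessages(simulate_study(arch, 500, 500, 100, seed = 41))
  dir <- withr::local_tempdir()
  write_study(study, dir)
  exp_back <- read_sumstats(file.path(dir, "exposure_gwas.tsv"),
                            trait = "exposure")
  expect_equal(exp_back$variants$beta, study$exposure_stats$variants$beta,
               tolerance = 1e-12)
  sets_back <- read_gene_sets(file.path(dir, "cell_sets.gmt"))
  expect_equal(lengths(sets_back), lengths(study$cell_sets))
  genes_back <- read_gene_annotation(file.path(dir, "genes.bed"))
  expect_equal(genes_back$start, study$genes$start)
  ld_back <- read_dosage_matrix(file.path(dir, "ld_reference.tsv"))
  expect_equal(ld_back$dosages, study$ld_ref$dosages)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$alpha_true, study$truth$alpha_true)
})
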