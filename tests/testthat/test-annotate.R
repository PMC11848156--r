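# exhaustive interval-membership enumeration, independent of the
# production window arithmetic
interval_oracle <- function(snps, genes, up, down, strand_aware = TRUE) {
  hits <- list()
  for (i in seq_len(nrow(snps))) {
    for (j in seq_len(nrow(genes))) {
      g <- genes[j, ]
      if (!g$protein_coding || g$chrom != snps$chrom[i]) next
      lo <- if (strand_aware && g$strand == "-") g$start - down else g$start - up
      hi <- if (strand_aware && g$strand == "-") g$end + up else g$end + down
      if (snps$pos[i] >= lo && snps$pos[i] <= hi) {
        hits[[length(hits) + 1L]] <- c(snps$snp_id[i], g$gene_id)
      }
    }
  }
  if (!length(hits)) return(character(0))
  sort(vapply(hits, paste, "", collapse = ":"))
}

test_that("SNP-to-gene windows are asymmetric, strand-aware, and boundary-exact", {
  genes <- toy_genes(c("Gp", "Gm", "Gnc"), chrom = "1",
                     start = c(10000L, 50000L, 90000L),
                     end = c(20000L, 60000L, 95000L),
                     strand = c("+", "-", "+"),
                     protein_coding = c(TRUE, TRUE, FALSE))
  snps <- data.frame(
    snp_id = sprintf("s%d", 1:8), chrom = "1",
    pos = c(8000L,   # + gene: exactly start - 2000 -> mapped
            7999L,   # one bp beyond the upstream window -> unmapped
            20500L,  # + gene: exactly end + 500 -> mapped
            20501L,  # end + 501 -> unmapped
            49500L,  # - gene: start - 500 (3' side) -> mapped
            62000L,  # - gene: end + 2000 (5' side) -> mapped
            49499L,  # one bp too far on the 3' side -> unmapped
            91000L), # inside a non-coding gene -> unmapped
    stringsAsFactors = FALSE)
  m <- map_snps_to_genes(snps, genes)
  expect_setequal(paste(m$snp_id, m$gene_id),
                  c("s1 Gp", "s3 Gp", "s5 Gm", "s6 Gm"))
  # distance is 0 inside the body, else bp to the nearer edge
  expect_equal(m$distance[m$snp_id == "s1"], 2000L)

  # strand-agnostic mode treats every gene like "+"
  m2 <- map_snps_to_genes(snps, genes, strand_aware = FALSE)
  expect_true("s7" %in% m2$snp_id)   # 49499 within start - 2000 of Gm
  expect_false("s6" %in% m2$snp_id)  # 62000 beyond end + 500 of Gm
})

test_that("random SNP/gene toys match the exhaustive interval oracle and
           window enlargement is monotone", {
  set.seed(21)
  for (rep in 1:10) {
    genes <- toy_genes(sprintf("G%d", 1:5),
                       chrom = sample(c("1", "2"), 5, TRUE),
                       start = sample.int(50000, 5), end = 0,
                       strand = sample(c("+", "-"), 5, TRUE),
                       protein_coding = sample(c(TRUE, TRUE, TRUE, FALSE), 5, TRUE))
    genes$end <- genes$start + sample.int(5000, 5)
    snps <- data.frame(snp_id = sprintf("s%02d", 1:15),
                       chrom = sample(c("1", "2"), 15, TRUE),
                       pos = sample.int(60000, 15), stringsAsFactors = FALSE)
    m <- map_snps_to_genes(snps, genes, 2000, 500)
    expect_identical(sort(paste(m$snp_id, m$gene_id, sep = ":")),
                     interval_oracle(snps, genes, 2000, 500))
    # monotone in the windows: enlarging never unmaps
    m_big <- map_snps_to_genes(snps, genes, 5000, 3000)
    expect_true(all(paste(m$snp_id, m$gene_id) %in%
                      paste(m_big$snp_id, m_big$gene_id)))
  }
})

test_that("dedup keeps the smallest-p SNP per gene and resolves multi-gene
           SNPs by proximity", {
  genes <- toy_genes(c("A", "B"), chrom = "1",
                     start = c(1000L, 9000L), end = c(10000L, 20000L))
  # gene A has three SNPs at p 0.1 / 0.01 / 0.5 -> the p=0.01 one is kept
  snps <- data.frame(snp_id = c("s1", "s2", "s3", "s4"), chrom = "1",
                     pos = c(2000L, 3000L, 4000L, 15000L),
                     stringsAsFactors = FALSE)
  exposure <- toy_sumstats(4, snp_id = c("s1", "s2", "s3", "s4"),
                           pos = snps$pos, pval = c(0.1, 0.01, 0.5, 0.2))
  m <- map_snps_to_genes(snps, genes)
  dd <- dedup_one_snp_per_gene(m, exposure, genes)
  expect_equal(dd$snp_id[dd$gene_id == "A"], "s2")
  expect_equal(dd$snp_id[dd$gene_id == "B"], "s4")
  expect_false(anyDuplicated(dd$gene_id) > 0)
  expect_false(anyDuplicated(dd$snp_id) > 0)

  # a SNP in the A/B overlap winning both genes goes to the nearer body
  snps5 <- rbind(snps, data.frame(snp_id = "s5", chrom = "1", pos = 9500L))
  exposure3 <- toy_sumstats(5, snp_id = c("s1", "s2", "s3", "s4", "s5"),
                            pos = snps5$pos,
                            pval = c(0.9, 0.9, 0.9, 0.9, 1e-4))
  m3 <- map_snps_to_genes(snps5, genes)
  dd3 <- dedup_one_snp_per_gene(m3, exposure3, genes)
  # s5 wins both genes; distance 0 to both bodies; tie -> smaller start (A)
  expect_equal(dd3$gene_id[dd3$snp_id == "s5"], "A")
  expect_false("A" %in% dd3$gene_id[dd3$snp_id != "s5"])

  # mapped SNP absent from exposure is a data error
  expect_error(dedup_one_snp_per_gene(m, toy_sumstats(2, snp_id = c("s1", "s2"),
                                                      pos = c(1L, 2L)), genes),
               "missing from exposure")

  # counting oracle: retained rows = genes with at least one mapped SNP
  set.seed(31)
  genes_r <- toy_genes(sprintf("G%d", 1:6), chrom = "1",
                       start = seq(1000L, by = 30000L, length.out = 6), end = 0)
  genes_r$end <- genes_r$start + 10000L
  snps_r <- data.frame(snp_id = sprintf("r%02d", 1:30), chrom = "1",
                       pos = sample(1000:180000, 30), stringsAsFactors = FALSE)
  exp_r <- toy_sumstats(30, snp_id = snps_r$snp_id, pos = snps_r$pos,
                        pval = runif(30))
  m_r <- map_snps_to_genes(snps_r, genes_r)
  dd_r <- dedup_one_snp_per_gene(m_r, exp_r, genes_r)
  expect_equal(nrow(dd_r), length(unique(m_r$gene_id)))
})

test_that("marker enrichment recovers planted markers and matches the exact
           hypergeometric oracle", {
  # a gene expressed in exactly one cell type is that type's marker
  expr <- matrix(5, 20, 4, dimnames = list(sprintf("g%02d", 1:20),
                                           c("A", "B", "C", "D")))
  expr["g01", ] <- c(200, 0, 0, 0)
  res <- score_marker_enrichment(expr)
  expect_true("g01" %in% res$sets$A)
  rec <- res$records[res$records$gene_id == "g01" & res$records$cell_type == "A", ]
  expect_equal(rec$p_hyper, min(res$records$p_hyper))

  # perfectly uniform expression yields empty sets
  res_u <- score_marker_enrichment(matrix(7, 30, 4,
                                          dimnames = list(sprintf("u%02d", 1:30),
                                                          c("A", "B", "C", "D"))))
  expect_true(all(lengths(res_u$sets) == 0L))

  # tail probabilities equal exact combinatorial summation on a 50-gene toy
  set.seed(41)
  expr <- matrix(rpois(50 * 4, 20), 50, 4,
                 dimnames = list(sprintf("t%02d", 1:50), c("A", "B", "C", "D")))
  res <- score_marker_enrichment(expr, bin_quantile = NULL)
  units <- round(expr)
  for (pick in sample.int(nrow(res$records), 25)) {
    r <- res$records[pick, ]
    x <- units[r$gene_id, r$cell_type]
    white <- sum(units[r$gene_id, ])
    drawn <- sum(units[, r$cell_type])
    expect_equal(r$p_hyper,
                 hyper_tail_oracle(x, white, sum(units) - white, drawn),
                 tolerance = 1e-9)
  }

  # fdr is BH within cell type, never below the raw p
  expect_true(all(res$records$fdr >= res$records$p_hyper - 1e-15))

  # all-zero rows are skipped with a warning
  expr0 <- expr; expr0[3, ] <- 0
  expect_warning(res0 <- score_marker_enrichment(expr0), "all-zero")
  expect_false(rownames(expr)[3] %in% res0$records$gene_id)
})

test_that("label-shuffled expression yields smaller marker sets than planted
           fixtures", {
  set.seed(51)
  # each type holds < 10% of genes, as in the 14-type partition, so the
  # top-decile bin can accommodate a type's full marker complement
  sets <- lapply(stats::setNames(1:12, paste0("T", 1:12)),
                 function(i) sprintf("g%d_%d", i, 1:8))
  expr <- simulate_expression(sets, seed = 51, base_mean = 10)
  planted <- sum(lengths(score_marker_enrichment(expr)$sets))
  expect_gte(planted, 80)  # most of the 96 planted markers recovered
  shuffled_sizes <- vapply(1:50, function(i) {
    # destroy the gene-type pairing: every expression value lands on a
    # random (gene, type) cell
    ex <- matrix(sample(expr), nrow(expr), ncol(expr),
                 dimnames = dimnames(expr))
    sum(lengths(suppressWarnings(score_marker_enrichment(ex)$sets)))
  }, 0)
  expect_lt(mean(shuffled_sizes), planted)
})

test_that("cell-type SNP sets follow the deduped map and flag empty sets", {
  map <- data.frame(snp_id = c("s1", "s2", "s3"),
                    gene_id = c("G1", "G2", "G3"),
                    distance = 0L, stringsAsFactors = FALSE)
  sets <- list(A = c("G1", "G2"), B = "G3", C = "G9", D = c("G1", "G3"))
  expect_message(out <- build_cell_snp_sets(map, sets), "empty SNP set")
  expect_setequal(out$A, c("s1", "s2"))
  expect_equal(out$B, "s3")
  expect_equal(out$C, character(0))
  expect_equal(attr(out, "empty_sets"), "C")
  # shared markers place a SNP in several sets by default
  expect_setequal(out$D, c("s1", "s3"))
  # "first" policy makes the sets disjoint
  out1 <- suppressMessages(build_cell_snp_sets(map, sets, "first"))
  expect_equal(out1$D, character(0))
  # disjoint marker sets give disjoint SNP sets
  expect_length(intersect(out$A, out$B), 0)
})
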