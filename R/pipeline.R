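#' Run the full cell-type-partitioned PRS pipeline
#'
#' Executes every stage on one study (simulated or loaded from disk):
#'
#' 1. variant QC (MAF/INFO filters) and fixed-region exclusion
#'    (APOE, MHC) on the exposure GWAS;
#' 2. greedy LD clumping against the reference panel, yielding the
#'    uncorrelated index-SNP pool;
#' 3. SNP-to-gene annotation with asymmetric strand-aware windows,
#'    one-SNP-per-gene deduplication, and per-cell-type SNP sets;
#' 4. harmonization of exposure and outcome summary statistics and the
#'    IVW (gtx) threshold scan over the whole-genome score and all cell
#'    scores;
#' 5. family-wise error control over the cell-set x threshold family;
#' 6. a set-size-matched permutation null for every FWE-significant
#'    cell score (pool = the gene-mapped universe at the matching
#'    threshold);
#' 7. leave-set-out attenuation for every FWE-significant cell score;
#' 8. split-sample replication with fixed-effect meta-analysis;
#' 9. the APOE re-inclusion sensitivity comparison.
#'
#' @param study a `sim_study` (or a list with the same fields:
#'   `exposure_stats`, `outcome$discovery/replication/combined`,
#'   `ld_ref`, `genes`, `cell_sets`).
#' @param cfg a [prs_config].
#' @return List of class `prs_pipeline_result` with elements `qc`
#'   (counts), `clump` (clump_result), `snp_gene_map`, `cell_snp_sets`,
#'   `scan` (FWE-annotated combined-sample scan table), `permutation`
#'   (named list of permutation_result), `attenuation` (named list),
#'   `replication` (replicate_and_combine output), `sensitivity_apoe`,
#'   `config`.
#' @export
run_pipeline <- function(study, cfg = prs_config()) {
  exposure <- study$exposure_stats

  # --- QC + region exclusion
  filtered <- filter_variants(exposure, cfg$maf_min, cfg$info_min)
  qc <- exclude_regions(filtered, cfg$excluded_regions)
  qc_log <- c(attr(filtered, "filter_log"),
              removed_regions = sum(attr(qc, "region_log")))

  # --- clumping
  cl <- clump(qc, study$ld_ref, cfg$clump_window_kb, cfg$clump_r2_max,
              cfg$missing_ld_policy)
  clumped <- subset_sumstats(qc, cl$retained)

  # --- gene annotation + cell SNP sets
  map_raw <- map_snps_to_genes(clumped$variants, study$genes,
                               cfg$upstream_bp, cfg$downstream_bp,
                               cfg$strand_aware_windows)
  map <- dedup_one_snp_per_gene(map_raw, clumped, study$genes)
  cell_snp_sets <- build_cell_snp_sets(map, study$cell_sets,
                                       cfg$multi_set_snp_policy)
  nonempty_sets <- cell_snp_sets[lengths(cell_snp_sets) > 0L]

  # --- association scan on the combined outcome + FWE
  combined <- study$outcome$combined
  pairs <- harmonize(clumped, combined, cfg$palindromic_policy)
  scan <- threshold_scan(pairs, combined$n_total, cfg$p_thresholds,
                         nonempty_sets, include_whole_genome = TRUE,
                         pseudo_r2_form = cfg$pseudo_r2_form)
  scan <- fwe_correct(scan, cfg$fwe_alpha, cfg$fwe_method,
                      exclude_sets = "whole_genome")

  # --- permutation null for FWE-significant cell scores; pool is the
  #     gene-mapped SNP universe at the matching threshold
  gene_pairs <- pairs[pairs$snp_id %in% map$snp_id, , drop = FALSE]
  sig <- scan[scan$significant & scan$set != "whole_genome", , drop = FALSE]
  permutation <- list()
  attenuation <- list()
  if (nrow(sig)) {
    # one permutation/attenuation per significant set, at its best threshold
    best <- sig[order(sig$set, sig$p), , drop = FALSE]
    best <- best[!duplicated(best$set), , drop = FALSE]
    for (i in seq_len(nrow(best))) {
      set_name <- best$set[i]
      thr <- best$threshold[i]
      inst <- build_instrument(pairs, thr,
                               snp_subset = cell_snp_sets[[set_name]],
                               name = set_name)
      pool <- build_instrument(gene_pairs, thr, name = "pool")$snps
      permutation[[set_name]] <- permutation_null(
        inst, pool, combined$n_total, cfg$n_perm,
        rng_substream(cfg$rng_seed, paste0("perm_", set_name)))
      attenuation[[set_name]] <- leave_set_out(
        pairs, cell_snp_sets[[set_name]], thr, combined$n_total)
    }
  }

  # --- split-sample replication + meta-analysis
  replication <- replicate_and_combine(
    clumped, study$outcome$discovery, study$outcome$replication,
    combined, nonempty_sets, cfg$p_thresholds,
    replication_p = cfg$replication_p, palindromic = cfg$palindromic_policy)

  # --- APOE re-inclusion sensitivity (QC branch without region exclusion)
  sensitivity_apoe <- NULL
  apoe_region <- cfg$excluded_regions[cfg$excluded_regions$label == "APOE", ,
                                      drop = FALSE]
  if (nrow(apoe_region)) {
    cl_keep <- clump(filtered, study$ld_ref, cfg$clump_window_kb,
                     cfg$clump_r2_max, cfg$missing_ld_policy)
    pairs_keep <- harmonize(subset_sumstats(filtered, cl_keep$retained),
                            combined, cfg$palindromic_policy)
    sensitivity_apoe <- sensitivity_include_region(
      pairs_keep, apoe_region, max(cfg$p_thresholds), combined$n_total)
  }

  structure(
    list(qc = qc_log, clump = cl, snp_gene_map = map,
         cell_snp_sets = cell_snp_sets, pairs = pairs, scan = scan,
         permutation = permutation, attenuation = attenuation,
         replication = replication, sensitivity_apoe = sensitivity_apoe,
         config = cfg),
    class = "prs_pipeline_result"
  )
}

#' @export
print.prs_pipeline_result <- function(x, ...) {
  cat("<prs_pipeline_result>\n")
  cat(sprintf("  QC: %d -> %d variants; clumped to %d index SNPs; %d gene-mapped\n",
              x$qc[["n_in"]], x$qc[["n_out"]] - x$qc[["removed_regions"]],
              length(x$clump$retained), nrow(x$snp_gene_map)))
  sig <- x$scan[x$scan$significant %in% TRUE, , drop = FALSE]
  cat(sprintf("  scan: %d fits, %d FWE-significant cell scores\n",
              nrow(x$scan), length(unique(sig$set))))
  invisible(x)
}

#' Rank cell scores by association strength
#'
#' Per cell set, the best (largest) |z| across thresholds — the ordering
#' used to ask which cell type's score explains the outcome best.
#'
#' @param scan a [threshold_scan] table.
#' @return data.frame `set`, `best_z`, `best_threshold`, `rank`,
#'   whole-genome excluded, strongest first.
#' @export
rank_cell_scores <- function(scan) {
  cells <- scan[scan$set != "whole_genome", , drop = FALSE]
  if (!nrow(cells)) return(data.frame(set = character(0), best_z = numeric(0),
                                      best_threshold = numeric(0),
                                      rank = integer(0)))
  ord <- order(cells$set, -abs(cells$z))
  cells <- cells[ord, , drop = FALSE]
  best <- cells[!duplicated(cells$set), , drop = FALSE]
  best <- best[order(-abs(best$z)), , drop = FALSE]
  data.frame(set = best$set, best_z = best$z,
             best_threshold = best$threshold,
             rank = seq_len(nrow(best)), stringsAsFactors = FALSE)
}

#' Write pipeline result tables to a directory
#'
#' Emits the scan table (TSV), the clump assignments (TSV), the deduped
#' SNP-gene map (TSV), the cell SNP sets (GMT of snp_ids), the
#' replication meta table (TSV), and a JSON summary of permutation,
#' attenuation, and sensitivity results plus a small run manifest.
#'
#' @param res a [run_pipeline] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_results <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) data.table::fwrite(x, file.path(dir, f), sep = "\t")
  tsv(res$scan, "association_scan.tsv")
  clump_tab <- rbind(
    data.frame(snp_id = res$clump$retained, status = "index",
               index_snp = res$clump$retained, stringsAsFactors = FALSE),
    data.frame(snp_id = names(res$clump$removed), status = "clumped",
               index_snp = unname(res$clump$removed), stringsAsFactors = FALSE)
  )
  tsv(clump_tab, "clump_assignments.tsv")
  tsv(res$snp_gene_map, "snp_gene_map.tsv")
  write_gene_sets(res$cell_snp_sets[lengths(res$cell_snp_sets) > 0L],
                  file.path(dir, "cell_snp_sets.gmt"))
  tsv(res$replication$meta, "replication_meta.tsv")
  summarize_perm <- function(p) p[c("observed_stat", "null_mean", "null_sd",
                                    "z_emp", "p_two_tailed", "p_empirical",
                                    "n_perm")]
  summarize_att <- function(a) a[c("alpha_full", "alpha_complement",
                                   "z_diff", "p_diff", "n_removed")]
  summary <- list(
    qc = as.list(res$qc),
    n_clumped = length(res$clump$retained),
    n_gene_mapped = nrow(res$snp_gene_map),
    permutation = lapply(res$permutation, summarize_perm),
    attenuation = lapply(res$attenuation, summarize_att),
    sensitivity_apoe = if (!is.null(res$sensitivity_apoe)) list(
      alpha_with = res$sensitivity_apoe$fit_with$alpha_hat,
      alpha_without = res$sensitivity_apoe$fit_without$alpha_hat,
      z_with = res$sensitivity_apoe$fit_with$z,
      z_without = res$sensitivity_apoe$fit_without$z,
      n_region_snps = res$sensitivity_apoe$n_region_snps),
    config = lapply(unclass(res$config), function(v)
      if (is.data.frame(v)) NULL else v),
    package_version = as.character(utils::packageVersion("ctprs")),
    seed = res$config$rng_seed
  )
  jsonlite::write_json(summary, file.path(dir, "pipeline_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
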