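#!/usr/bin/env Rscript
# Validation battery for the strongest cell score: the set-size-matched
# permutation null (1000 draws), the leave-set-out attenuation test,
# split-sample replication with fixed-effect meta-analysis, and the APOE
# re-inclusion sensitivity comparison.
source("analysis/00_config.R")

study <- load_study_files()
cfg <- study_config()
clumped <- read_sumstats(file.path(STUDY_DIR, "exposure_clumped.tsv"),
                         trait = "exposure", n_total = N_IND)
cell_snp_sets <- read_gene_sets(file.path(STUDY_DIR, "cell_snp_sets.gmt"))
map <- read.delim(file.path(RESULTS_DIR, "03_snp_gene_map.tsv"))

combined <- study$outcome$combined
pairs <- harmonize(clumped, combined)
scan <- fwe_correct(threshold_scan(pairs, combined$n_total, cfg$p_thresholds,
                                   unclass(cell_snp_sets)),
                    cfg$fwe_alpha, cfg$fwe_method)
rk <- rank_cell_scores(scan)
top_set <- rk$set[1]
top_thr <- rk$best_threshold[1]

# permutation null: same set size, same threshold, pool = gene-mapped SNPs
inst <- build_instrument(pairs, top_thr,
                         snp_subset = cell_snp_sets[[top_set]], name = top_set)
pool <- build_instrument(pairs[pairs$snp_id %in% map$snp_id, ], top_thr)$snps
perm <- permutation_null(inst, pool, combined$n_total, cfg$n_perm,
                         rng_substream(cfg$rng_seed, paste0("perm_", top_set)))
message(top_set, " vs ", cfg$n_perm, " size-matched random scores: Z = ",
        signif(perm$z_emp, 3), ", two-tailed p = ",
        signif(perm$p_two_tailed, 2), ", empirical p = ",
        signif(perm$p_empirical, 2))

# leave-set-out attenuation
att <- leave_set_out(pairs, cell_snp_sets[[top_set]], top_thr,
                     combined$n_total)
message("leave-", top_set, "-out: complement alpha ",
        signif(att$alpha_complement, 3), " (p = ",
        signif(att$fit_complement$pval, 2), "), attenuation z = ",
        signif(att$z_diff, 3))

# split-sample replication + meta-analysis
repl <- replicate_and_combine(clumped, study$outcome$discovery,
                              study$outcome$replication, combined,
                              unclass(cell_snp_sets), cfg$p_thresholds,
                              cfg$replication_p)
write.table(repl$meta, file.path(RESULTS_DIR, "05_replication_meta.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
tg <- repl$meta[repl$meta$set == top_set, ]
message(top_set, " replicates (same sign, both p < ", cfg$replication_p,
        ") at ", sum(tg$consistent), "/", nrow(tg), " thresholds")

# APOE sensitivity: redo QC without region exclusion
filtered <- filter_variants(study$exposure_stats, cfg$maf_min, cfg$info_min)
cl_keep <- clump(filtered, study$ld_ref, cfg$clump_window_kb,
                 cfg$clump_r2_max)
pairs_keep <- harmonize(subset_sumstats(filtered, cl_keep$retained), combined)
apoe <- cfg$excluded_regions[cfg$excluded_regions$label == "APOE", ]
sens <- sensitivity_include_region(pairs_keep, apoe, max(cfg$p_thresholds),
                                   combined$n_total)
message("re-including APOE: whole-genome z ",
        signif(sens$fit_without$z, 3), " -> ", signif(sens$fit_with$z, 3),
        " (", sens$n_region_snps, " region SNPs)")

summary <- list(
  top_set = top_set, top_threshold = top_thr,
  permutation = perm[c("observed_stat", "null_mean", "null_sd", "z_emp",
                       "p_two_tailed", "p_empirical", "n_perm")],
  attenuation = att[c("alpha_full", "alpha_complement", "z_diff", "p_diff")],
  apoe = list(z_without = sens$fit_without$z, z_with = sens$fit_with$z,
              n_region_snps = sens$n_region_snps)
)
jsonlite::write_json(summary, file.path(RESULTS_DIR, "05_inference.json"),
                     auto_unbox = TRUE, digits = NA)
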