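#!/usr/bin/env Rscript
# Generate the synthetic two-sample study: an exposure GWAS (the score
# weights), an outcome GWAS split into discovery/replication plus the
# combined sample, an LD reference panel, gene annotations, and the 14
# cell-type gene sets — with the proportional exposure->outcome effect
# concentrated in the SMC set (5x enrichment, alpha_true = 0.3).
source("analysis/00_config.R")

arch <- study_arch()
message("simulating study: ", arch$n_snps, " SNPs, ", arch$n_genes,
        " genes, n = ", N_IND, " per cohort, target = ",
        arch$target_cell_type)
study <- simulate_study(arch, n_exposure = N_IND, n_outcome = N_IND,
                        n_ld_ref = N_LD_REF, seed = STUDY_SEED)
write_study(study, STUDY_DIR)

truth_by_class <- as.data.frame(table(study$meta$class))
names(truth_by_class) <- c("variant_class", "n_snps")
write.table(truth_by_class, file.path(RESULTS_DIR, "01_variant_classes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

n_causal <- length(study$truth$causal_ids)
message("wrote study to ", STUDY_DIR, ": ", nrow(study$meta), " SNPs (",
        n_causal, " causal, ",
        sum(study$truth$snp$causal &
              study$truth$snp$cell_type %in% arch$target_cell_type),
        " in the target set), exposure GWAS n = ",
        study$exposure_stats$n_total)
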