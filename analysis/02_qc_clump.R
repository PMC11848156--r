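#!/usr/bin/env Rscript
# QC the exposure GWAS (MAF >= 0.01, INFO >= 0.9), strip the APOE and
# MHC regions, and LD-clump against the reference panel (+/-10 Mb,
# r^2 <= 0.001) to the uncorrelated index-SNP pool.
source("analysis/00_config.R")

study <- load_study_files()
cfg <- study_config()

filtered <- filter_variants(study$exposure_stats, cfg$maf_min, cfg$info_min)
qc <- exclude_regions(filtered, cfg$excluded_regions)
cl <- clump(qc, study$ld_ref, cfg$clump_window_kb, cfg$clump_r2_max)

clump_tab <- rbind(
  data.frame(snp_id = cl$retained, status = "index", index_snp = cl$retained),
  data.frame(snp_id = names(cl$removed), status = "clumped",
             index_snp = unname(cl$removed))
)
write.table(clump_tab, file.path(RESULTS_DIR, "02_clump_assignments.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_sumstats(subset_sumstats(qc, cl$retained),
               file.path(STUDY_DIR, "exposure_clumped.tsv"))

flog <- attr(filtered, "filter_log")
rlog <- attr(qc, "region_log")
message("QC: ", flog[["n_in"]], " -> ", flog[["n_out"]], " variants (",
        flog[["removed_low_maf"]], " low MAF, ",
        flog[["removed_low_info"]], " low INFO); regions removed ",
        paste(names(rlog), rlog, collapse = ", "))
message("clumping retained ", length(cl$retained), " index SNPs (",
        length(cl$removed), " absorbed)")
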