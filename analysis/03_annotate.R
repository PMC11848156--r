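#!/usr/bin/env Rscript
# Map the clumped SNPs to proximal protein-coding genes (2 kb upstream /
# 0.5 kb downstream, strand-aware), deduplicate to one SNP per gene, and
# assemble the 14 per-cell-type SNP sets.
source("analysis/00_config.R")

study <- load_study_files()
cfg <- study_config()
clumped <- read_sumstats(file.path(STUDY_DIR, "exposure_clumped.tsv"),
                         trait = "exposure", n_total = N_IND)

map_raw <- map_snps_to_genes(clumped$variants, study$genes,
                             cfg$upstream_bp, cfg$downstream_bp)
map <- dedup_one_snp_per_gene(map_raw, clumped, study$genes)
cell_snp_sets <- build_cell_snp_sets(map, study$cell_sets)

write.table(map, file.path(RESULTS_DIR, "03_snp_gene_map.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_gene_sets(cell_snp_sets[lengths(cell_snp_sets) > 0],
                file.path(STUDY_DIR, "cell_snp_sets.gmt"))
sizes <- data.frame(cell_type = names(cell_snp_sets),
                    n_snps = lengths(cell_snp_sets))
write.table(sizes, file.path(RESULTS_DIR, "03_cell_set_sizes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message(nrow(map_raw), " SNP-gene pairs -> ", nrow(map),
        " one-per-gene SNPs; cell-set sizes ",
        paste(sizes$cell_type, sizes$n_snps, sep = "=", collapse = ", "))
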