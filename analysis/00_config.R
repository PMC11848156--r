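# shared settings for the numbered analysis drivers: one synthetic study
# at the default conditions, one pipeline configuration, one seed
library(ctprs)

STUDY_SEED <- 1L
STUDY_DIR <- "scratch/study"
RESULTS_DIR <- "results"
N_IND <- 20000L
N_LD_REF <- 2504L

study_arch <- function() sim_architecture()
study_config <- function() prs_config(rng_seed = STUDY_SEED)

require_study <- function() {
  if (!file.exists(file.path(STUDY_DIR, "exposure_gwas.tsv"))) {
    stop("study files not found under ", STUDY_DIR,
         "; run analysis/01_simulate.R first", call. = FALSE)
  }
}

load_study_files <- function() {
  require_study()
  list(
    exposure_stats = read_sumstats(file.path(STUDY_DIR, "exposure_gwas.tsv"),
                                   trait = "exposure", n_total = N_IND),
    outcome = list(
      discovery = read_sumstats(file.path(STUDY_DIR, "outcome_discovery.tsv")),
      replication = read_sumstats(file.path(STUDY_DIR,
                                            "outcome_replication.tsv")),
      combined = read_sumstats(file.path(STUDY_DIR, "outcome_combined.tsv"))
    ),
    genes = read_gene_annotation(file.path(STUDY_DIR, "genes.bed")),
    cell_sets = read_gene_sets(file.path(STUDY_DIR, "cell_sets.gmt")),
    ld_ref = read_dosage_matrix(file.path(STUDY_DIR, "ld_reference.tsv")),
    truth = jsonlite::read_json(file.path(STUDY_DIR, "truth.json"))
  )
}

dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)
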