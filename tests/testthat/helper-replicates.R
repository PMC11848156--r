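# 50 seeded full-scale pipeline replicates (n_ind = 20000, n_snps = 3000,
# alpha_true = 0.3, 5x target enrichment), computed once per test run and
# shared by the end-to-end recovery tests
.replicate_cache <- new.env(parent = emptyenv())

headline_replicates <- function(n_rep = 50) {
  key <- paste0("reps", n_rep)
  if (!is.null(.replicate_cache[[key]])) return(.replicate_cache[[key]])
  arch <- sim_architecture()  # the study conditions: defaults
  rows <- lapply(seq_len(n_rep), function(seed) {
    study <- suppressMessages(
      simulate_study(arch, n_exposure = 20000, n_outcome = 20000,
                     n_ld_ref = 2504, seed = seed))
    res <- suppressMessages(run_pipeline(study, prs_config(rng_seed = seed)))
    target <- study$truth$target_cell_type
    rk <- rank_cell_scores(res$scan)
    meta_tab <- res$replication$meta
    att <- res$attenuation[[target]]
    data.frame(
      seed = seed,
      ranked_first = rk$set[1] == target,
      fwe_pass = any(res$scan$significant[res$scan$set == target]),
      perm_pass = target %in% names(res$permutation) &&
        res$permutation[[target]]$p_empirical < 0.05,
      replication_pass = any(meta_tab$consistent[meta_tab$set == target]),
      complement_significant = !is.null(att) &&
        att$fit_complement$pval < 0.05,
      attenuation_p = if (is.null(att)) NA_real_ else att$p_diff
    )
  })
  out <- do.call(rbind, rows)
  .replicate_cache[[key]] <- out
  out
}
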