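#' Family-wise error correction of a scan table
#'
#' Bonferroni (default) or Holm adjustment over the tests actually
#' performed: T equals the number of fitted (set, threshold) rows in the
#' family — skipped empty instruments never enter T. The whole-genome
#' score is, by default, not part of the family (the family is the cell
#' sets x thresholds); its rows receive `p_adj = NA`.
#'
#' @param results scan table from [threshold_scan].
#' @param alpha family-wise error rate (default 0.05).
#' @param method "bonferroni" (default) or "holm".
#' @param exclude_sets set names excluded from the family (default
#'   "whole_genome").
#' @return The table with columns `p_adj` and `significant` appended and
#'   `attr(result, "n_tests")` recording T.
#' @export
fwe_correct <- function(results, alpha = 0.05,
                        method = c("bonferroni", "holm"),
                        exclude_sets = "whole_genome") {
  method <- match.arg(method)
  if (!nrow(results)) stop("empty results table")
  in_family <- !(results$set %in% exclude_sets)
  n_tests <- sum(in_family)
  results$p_adj <- NA_real_
  if (n_tests) {
    results$p_adj[in_family] <-
      stats::p.adjust(results$p[in_family], method = method)
  }
  results$significant <- !is.na(results$p_adj) & results$p_adj < alpha
  attr(results, "n_tests") <- n_tests
  results
}

#' Set-size-matched permutation null for one score
#'
#' Tests whether a named SNP set's association strength could arise
#' from any same-sized draw of SNPs at the same p-threshold: `n_perm`
#' sets of size |target| are drawn uniformly without replacement from
#' the pool of harmonized pairs, each is fitted with the IVW estimator,
#' and the observed |alpha| is compared against the null distribution of
#' |alpha|. Reports both the normal-approximation two-tailed p from
#' `z_emp = (obs - mean) / sd` and the add-one empirical p
#' `(1 + #[null >= obs]) / (n_perm + 1)`. Draws exclude nothing: the
#' observed set may be re-drawn by chance.
#'
#' @param target a fitted [score_instrument] (the observed set).
#' @param pool harmonized pairs already restricted to the matching
#'   p-threshold universe; must contain the target's SNPs and exceed the
#'   target's size.
#' @param n_outcome outcome GWAS sample size.
#' @param n_perm number of permuted sets (default 1000).
#' @param seed integer seed for the draw substream.
#' @return List of class `permutation_result`: `observed_stat` (|alpha|),
#'   `null_mean`, `null_sd`, `z_emp`, `p_two_tailed`, `p_empirical`,
#'   `n_perm`, `seed`, `null_stats`.
#' @export
permutation_null <- function(target, pool, n_outcome, n_perm = 1000,
                             seed = 1L) {
  stopifnot(inherits(target, "score_instrument"))
  m <- nrow(target$snps)
  if (m == 0L) stop("empty target set")
  n_pool <- nrow(pool)
  if (n_pool <= m) stop("pool must be larger than the target set")
  if (!all(target$snps$snp_id %in% pool$snp_id)) {
    stop("target set is not a subset of the pool")
  }
  if (n_pool < 2L * m) {
    warning("pool smaller than twice the target set; null may be degenerate")
  }
  obs <- abs(gtx_association(target, n_outcome)$alpha_hat)

  num <- pool$w * pool$b / pool$s^2
  den <- pool$w^2 / pool$s^2
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  null_stats <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n_pool, m)
    abs(sum(num[idx]) / sum(den[idx]))
  }, 0.0)
  null_mean <- mean(null_stats)
  null_sd <- stats::sd(null_stats)
  if (is.na(null_sd) || null_sd == 0) stop("degenerate permutation null (sd = 0)")
  z_emp <- (obs - null_mean) / null_sd
  structure(
    list(observed_stat = obs, null_mean = null_mean, null_sd = null_sd,
         z_emp = z_emp,
         p_two_tailed = 2 * stats::pnorm(-abs(z_emp)),
         p_empirical = (1 + sum(null_stats >= obs)) / (n_perm + 1),
         n_perm = n_perm, seed = seed, null_stats = null_stats),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> obs=%.4g null=%.4g+/-%.3g Z=%.2f p=%.3g p_emp=%.3g (n_perm=%d)\n",
    x$observed_stat, x$null_mean, x$null_sd, x$z_emp, x$p_two_tailed,
    x$p_empirical, x$n_perm))
  invisible(x)
}

#' Leave-set-out attenuation test
#'
#' Removes a cell type's SNPs from the full score and asks whether the
#' remaining association is significantly attenuated. For nested IVW
#' fits the full-score and complement estimates satisfy
#' var(alpha_full - alpha_complement) = se_complement^2 - se_full^2 (the
#' precision-weighting identity), giving
#' `z_diff = (alpha_full - alpha_complement) / sqrt(se_c^2 - se_f^2)`
#' with a two-tailed normal p.
#'
#' @param pairs harmonized pairs.
#' @param cell_set snp_ids to leave out (must be within the instrument).
#' @param threshold exposure p-value threshold for the full instrument.
#' @param n_outcome outcome GWAS sample size.
#' @return List of class `attenuation_result`: `fit_full`,
#'   `fit_complement` (both [gtx_association] results), `alpha_full`,
#'   `alpha_complement`, `z_diff`, `p_diff`, `n_removed`.
#' @export
leave_set_out <- function(pairs, cell_set, threshold, n_outcome) {
  full <- build_instrument(pairs, threshold, name = "full")
  if (full$empty) stop("full instrument is empty at this threshold")
  comp_ids <- setdiff(full$snps$snp_id, cell_set)
  if (!length(comp_ids)) stop("complement is empty: set covers the instrument")
  comp <- build_instrument(pairs, threshold, snp_subset = comp_ids,
                           name = "complement")
  fit_f <- gtx_association(full, n_outcome)
  fit_c <- gtx_association(comp, n_outcome)
  var_diff <- fit_c$se_alpha^2 - fit_f$se_alpha^2
  d <- fit_f$alpha_hat - fit_c$alpha_hat
  if (var_diff < -1e-12) {
    stop("internal consistency error: nested complement more precise than full fit")
  }
  z_diff <- if (var_diff <= 0) {
    if (abs(d) > 1e-10) {
      stop("internal consistency error: zero difference variance with nonzero difference")
    }
    0
  } else d / sqrt(var_diff)
  structure(
    list(fit_full = fit_f, fit_complement = fit_c,
         alpha_full = fit_f$alpha_hat, alpha_complement = fit_c$alpha_hat,
         z_diff = z_diff, p_diff = 2 * stats::pnorm(-abs(z_diff)),
         n_removed = fit_f$m_snps - fit_c$m_snps),
    class = "attenuation_result"
  )
}

#' Split-sample replication and fixed-effect meta-analysis
#'
#' Applies the same instrument definitions (sets x thresholds, built
#' from the one exposure GWAS) to the discovery, replication, and
#' combined outcome GWAS. For every (set, threshold) fitted in both
#' split halves, reports the precision-weighted fixed-effect
#' meta-analysis (`alpha_meta`, `se_meta`, `z_meta`, `p_meta`) alongside
#' the combined-sample fit, and a consistency flag: discovery and
#' replication alphas share sign and both nominal p-values fall below
#' `replication_p`. Instruments empty in either half are excluded from
#' the meta-analysis.
#'
#' @param exposure exposure [sumstats].
#' @param discovery,replication,combined outcome [sumstats] triple from
#'   a split-sample design.
#' @param snp_sets named list of snp_id vectors (cell-type sets).
#' @param thresholds p-value thresholds.
#' @param replication_p nominal significance required in each half
#'   (default 0.05).
#' @param palindromic passed to [harmonize].
#' @return List with `discovery`, `replication`, `combined` scan tables
#'   and `meta`, a data.frame keyed by (set, threshold) with the two
#'   per-half fits, the meta fit, and `consistent`.
#' @export
replicate_and_combine <- function(exposure, discovery, replication, combined,
                                  snp_sets = NULL,
                                  thresholds = c(0.01, 0.5, 1.0),
                                  replication_p = 0.05,
                                  palindromic = "keep") {
  scan_one <- function(outcome) {
    pairs <- harmonize(exposure, outcome, palindromic)
    threshold_scan(pairs, n_outcome = outcome$n_total,
                   thresholds = thresholds, snp_sets = snp_sets)
  }
  tab_d <- scan_one(discovery)
  tab_r <- scan_one(replication)
  tab_c <- scan_one(combined)

  key <- function(t) paste(t$set, t$threshold)
  shared <- intersect(key(tab_d), key(tab_r))
  id <- match(shared, key(tab_d))
  ir <- match(shared, key(tab_r))
  ic <- match(shared, key(tab_c))
  prec_d <- 1 / tab_d$se[id]^2
  prec_r <- 1 / tab_r$se[ir]^2
  alpha_meta <- (tab_d$alpha[id] * prec_d + tab_r$alpha[ir] * prec_r) /
    (prec_d + prec_r)
  se_meta <- 1 / sqrt(prec_d + prec_r)
  z_meta <- alpha_meta / se_meta
  meta <- data.frame(
    set = tab_d$set[id], threshold = tab_d$threshold[id],
    alpha_discovery = tab_d$alpha[id], p_discovery = tab_d$p[id],
    alpha_replication = tab_r$alpha[ir], p_replication = tab_r$p[ir],
    alpha_combined = ifelse(is.na(ic), NA_real_, tab_c$alpha[ic]),
    p_combined = ifelse(is.na(ic), NA_real_, tab_c$p[ic]),
    alpha_meta = alpha_meta, se_meta = se_meta, z_meta = z_meta,
    p_meta = 2 * stats::pnorm(-abs(z_meta)),
    consistent = sign(tab_d$alpha[id]) == sign(tab_r$alpha[ir]) &
      tab_d$p[id] < replication_p & tab_r$p[ir] < replication_p,
    stringsAsFactors = FALSE
  )
  rownames(meta) <- NULL
  list(discovery = tab_d, replication = tab_r, combined = tab_c, meta = meta)
}

# all permutations of 1..n as a matrix (n! rows); n is tiny (<= 8)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Rank concordance between two sets of per-cell-type results
#'
#' Spearman rank correlation of a statistic (alpha by default) across
#' the shared set names of two result tables — used to ask whether two
#' analyses (e.g. two outcome traits, or this pipeline vs a published
#' ranking) order the cell types the same way. The two-tailed p-value
#' uses the t approximation, replaced by the exact permutation
#' distribution (enumeration over all n! rank orders) when n <= 8.
#'
#' @param results_a,results_b data.frames keyed by `set` with the
#'   statistic column; at least 4 shared keys required.
#' @param statistic column to rank (default "alpha").
#' @return List: `rho`, `p`, `n`, `method` ("exact" or "t-approx").
#' @export
rank_concordance <- function(results_a, results_b, statistic = "alpha") {
  shared <- intersect(results_a$set, results_b$set)
  n <- length(shared)
  if (n < 4L) stop("need at least 4 shared set names; got ", n)
  a <- results_a[[statistic]][match(shared, results_a$set)]
  b <- results_b[[statistic]][match(shared, results_b$set)]
  ra <- rank(a)
  rb <- rank(b)
  rho <- stats::cor(ra, rb)
  if (n <= 8L) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1L, function(p) stats::cor(ra, rb[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t-approx"
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' Sensitivity analysis: re-include an excluded region
#'
#' Compares the score association with and without a region's SNPs —
#' e.g. adding the APOE locus back to the whole-genome score to check
#' that its effect is consistent with prior observations. `pairs` must
#' come from a QC run that retained the region.
#'
#' @param pairs harmonized pairs built WITHOUT region exclusion.
#' @param region one-row data.frame (`chrom`, `start_bp`, `end_bp`).
#' @param threshold exposure p-value threshold.
#' @param n_outcome outcome GWAS sample size.
#' @return List: `fit_with`, `fit_without`, `delta_alpha`, `delta_z`,
#'   `n_region_snps`.
#' @export
sensitivity_include_region <- function(pairs, region, threshold, n_outcome) {
  in_region <- pairs$chrom == region$chrom[1L] &
    pairs$pos >= region$start_bp[1L] & pairs$pos <= region$end_bp[1L]
  with_inst <- build_instrument(pairs, threshold, name = "with_region")
  without_ids <- pairs$snp_id[!in_region]
  without_inst <- build_instrument(pairs, threshold, snp_subset = without_ids,
                                   name = "without_region")
  if (!any(in_region)) {
    warning("region contributes no SNPs; comparison is an identity")
  }
  fit_w <- gtx_association(with_inst, n_outcome)
  fit_wo <- gtx_association(without_inst, n_outcome)
  list(fit_with = fit_w, fit_without = fit_wo,
       delta_alpha = fit_w$alpha_hat - fit_wo$alpha_hat,
       delta_z = fit_w$z - fit_wo$z,
       n_region_snps = sum(with_inst$snps$snp_id %in% pairs$snp_id[in_region]))
}
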