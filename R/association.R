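#' Harmonize exposure and outcome summary statistics
#'
#' Inner-joins the two GWAS on snp_id and aligns the outcome effect to
#' the exposure's coded allele: when the outcome's coded allele equals
#' the exposure's other allele (and vice versa) the outcome beta is
#' negated; pairs whose allele sets differ entirely are dropped with a
#' log entry. Palindromic pairs (A/T or C/G) are strand-ambiguous; by
#' default they are kept and flagged, since both GWAS of a simulated or
#' strand-consistent study share one strand convention.
#'
#' @param exposure,outcome [sumstats] objects.
#' @param palindromic "keep" (default) or "drop".
#' @return data.frame of harmonized pairs: `snp_id`, `chrom`, `pos`,
#'   `allele_effect`, `allele_other`, `w` (exposure beta per coded-allele
#'   dose), `pval_exposure`, `b` (aligned outcome beta), `s` (outcome
#'   SE > 0), `palindromic`. Attributes `n_dropped_alleles`,
#'   `n_outcome` (outcome GWAS sample size).
#' @export
harmonize <- function(exposure, outcome, palindromic = c("keep", "drop")) {
  palindromic <- match.arg(palindromic)
  ev <- exposure$variants
  ov <- outcome$variants
  idx <- match(ev$snp_id, ov$snp_id)
  keep <- !is.na(idx)
  ev <- ev[keep, , drop = FALSE]
  ov <- ov[idx[keep], , drop = FALSE]
  if (!nrow(ev)) stop("no SNPs shared between exposure and outcome")

  same <- ev$allele_effect == ov$allele_effect &
    ev$allele_other == ov$allele_other
  flipped <- ev$allele_effect == ov$allele_other &
    ev$allele_other == ov$allele_effect
  mismatched <- !same & !flipped
  if (any(mismatched)) {
    message(sum(mismatched), " pair(s) dropped: allele sets differ")
  }
  ev <- ev[!mismatched, , drop = FALSE]
  ov <- ov[!mismatched, , drop = FALSE]
  flipped <- flipped[!mismatched]
  if (!nrow(ev)) stop("no allele-compatible SNPs shared between GWAS")

  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pal <- comp[ev$allele_effect] == ev$allele_other
  pairs <- data.frame(
    snp_id = ev$snp_id, chrom = ev$chrom, pos = ev$pos,
    allele_effect = ev$allele_effect, allele_other = ev$allele_other,
    w = ev$beta, pval_exposure = ev$pval,
    b = ifelse(flipped, -ov$beta, ov$beta), s = ov$se,
    palindromic = unname(pal),
    stringsAsFactors = FALSE
  )
  if (palindromic == "drop") {
    pairs <- pairs[!pairs$palindromic, , drop = FALSE]
    if (!nrow(pairs)) stop("no SNPs remain after dropping palindromic pairs")
  } else if (any(pairs$palindromic)) {
    message(sum(pairs$palindromic), " palindromic pair(s) kept and flagged")
  }
  rownames(pairs) <- NULL
  attr(pairs, "n_dropped_alleles") <- sum(mismatched)
  attr(pairs, "n_outcome") <- outcome$n_total
  pairs
}

#' Build a score instrument at an exposure p-value threshold
#'
#' Retains harmonized pairs with exposure p strictly below
#' `p_threshold`, optionally intersected with a named SNP subset (a
#' cell-type set, or a complement for leave-set-out analysis). The
#' strict comparison means a threshold of 1.0 excludes pairs with
#' p = 1.0 exactly.
#'
#' @param pairs harmonized pairs from [harmonize].
#' @param p_threshold exposure p-value threshold in (0, 1\].
#' @param snp_subset optional character vector of snp_ids.
#' @param name instrument label.
#' @return List of class `score_instrument` with `name`, `p_threshold`,
#'   `snps` (the retained pair rows) and `empty` flag.
#' @export
build_instrument <- function(pairs, p_threshold, snp_subset = NULL,
                             name = "whole_genome") {
  if (p_threshold <= 0 || p_threshold > 1) {
    stop("p_threshold must lie in (0, 1]")
  }
  keep <- pairs$pval_exposure < p_threshold
  if (!is.null(snp_subset)) keep <- keep & pairs$snp_id %in% snp_subset
  snps <- pairs[keep, , drop = FALSE]
  rownames(snps) <- NULL
  structure(
    list(name = name, p_threshold = p_threshold, snps = snps,
         empty = nrow(snps) == 0L),
    class = "score_instrument"
  )
}

#' @export
print.score_instrument <- function(x, ...) {
  cat(sprintf("<score_instrument> %s (p<%g): %d SNPs%s\n", x$name,
              x$p_threshold, nrow(x$snps), if (x$empty) " [EMPTY]" else ""))
  invisible(x)
}

#' Inverse-variance-weighted (gtx) risk-score association
#'
#' The summary-statistic regression of per-SNP outcome effects on
#' exposure weights with inverse-variance weighting — the two-sample
#' estimate of the outcome change per unit of the weighted allele score,
#' equivalent to the IVW estimator of two-sample Mendelian
#' randomization. With weights w (exposure beta per coded-allele dose),
#' aligned outcome betas b and outcome SEs s:
#' \deqn{\hat\alpha = \frac{\sum w b / s^2}{\sum w^2 / s^2},\qquad
#'       se(\hat\alpha) = \Big(\sum w^2/s^2\Big)^{-1/2}}
#' with `chi2 = (alpha/se)^2` tested against the 1-df chi-square, and a
#' pseudo variance explained derived from the likelihood-ratio
#' statistic, `pseudo_r2 = 1 - exp(-chi2 / n)` (the first-order form
#' `chi2 / n` is available via `pseudo_r2_form`). Exact when the SNPs
#' are mutually uncorrelated, hence the upstream clumping at r^2 <
#' 0.001.
#'
#' @param inst a non-empty [build_instrument] result (or a data.frame
#'   with columns `w`, `b`, `s`).
#' @param n_outcome outcome GWAS sample size (used only by the
#'   pseudo-R^2).
#' @param pseudo_r2_form "lrt" (default) or "first_order".
#' @return List of class `gtx_result`: `alpha_hat`, `se_alpha`, `z`,
#'   `chi2`, `pval`, `pseudo_r2`, `m_snps`, `n_outcome`, `name`,
#'   `p_threshold`.
#' @export
gtx_association <- function(inst, n_outcome,
                            pseudo_r2_form = c("lrt", "first_order")) {
  pseudo_r2_form <- match.arg(pseudo_r2_form)
  if (inherits(inst, "score_instrument")) {
    snps <- inst$snps
    name <- inst$name
    p_threshold <- inst$p_threshold
  } else {
    snps <- inst
    name <- "instrument"
    p_threshold <- NA_real_
  }
  if (!nrow(snps)) stop("empty instrument: association undefined")
  if (any(snps$s <= 0)) stop("outcome SE must be strictly positive")
  if (n_outcome <= 2) stop("n_outcome must exceed 2")
  w <- snps$w
  b <- snps$b
  prec <- 1 / snps$s^2
  denom <- sum(w^2 * prec)
  if (denom == 0) stop("all weights zero: association undefined")
  alpha <- sum(w * b * prec) / denom
  se <- 1 / sqrt(denom)
  z <- alpha / se
  chi2 <- z^2
  structure(
    list(alpha_hat = alpha, se_alpha = se, z = z, chi2 = chi2,
         pval = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
         pseudo_r2 = if (pseudo_r2_form == "lrt") 1 - exp(-chi2 / n_outcome)
                     else chi2 / n_outcome,
         m_snps = nrow(snps), n_outcome = as.integer(n_outcome),
         name = name, p_threshold = p_threshold),
    class = "gtx_result"
  )
}

#' @export
print.gtx_result <- function(x, ...) {
  cat(sprintf(
    "<gtx_result> %s (p<%g): alpha=%.4g (se %.3g), z=%.3f, p=%.3g, pseudoR2=%.3g, m=%d\n",
    x$name, x$p_threshold, x$alpha_hat, x$se_alpha, x$z, x$pval,
    x$pseudo_r2, x$m_snps))
  invisible(x)
}

#' Scan score instruments over sets and thresholds
#'
#' Fits [gtx_association] for every combination of SNP set (plus the
#' whole-genome set when `include_whole_genome`) and exposure p-value
#' threshold. Empty instruments are skipped and recorded in
#' `attr(result, "skipped")`.
#'
#' @param pairs harmonized pairs from [harmonize].
#' @param n_outcome outcome GWAS sample size.
#' @param thresholds strictly increasing p-value thresholds.
#' @param snp_sets named list of snp_id vectors (may be NULL for a
#'   whole-genome-only scan).
#' @param include_whole_genome include the unrestricted instrument under
#'   the name "whole_genome" (default TRUE).
#' @param pseudo_r2_form passed to [gtx_association].
#' @return data.frame with one row per fitted (set, threshold):
#'   `set`, `threshold`, `m_snps`, `alpha`, `se`, `z`, `chi2`, `p`,
#'   `pseudo_r2`.
#' @export
threshold_scan <- function(pairs, n_outcome, thresholds = c(0.01, 0.5, 1.0),
                           snp_sets = NULL, include_whole_genome = TRUE,
                           pseudo_r2_form = c("lrt", "first_order")) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing")
  }
  pseudo_r2_form <- match.arg(pseudo_r2_form)
  sets <- snp_sets %||% list()
  if (include_whole_genome) {
    sets <- c(list(whole_genome = NULL), sets)
  }
  rows <- list()
  skipped <- character(0)
  for (set_name in names(sets)) {
    for (thr in thresholds) {
      inst <- build_instrument(pairs, thr, snp_subset = sets[[set_name]],
                               name = set_name)
      if (inst$empty) {
        skipped <- c(skipped, sprintf("%s@%g", set_name, thr))
        next
      }
      r <- gtx_association(inst, n_outcome, pseudo_r2_form)
      rows[[length(rows) + 1L]] <- data.frame(
        set = set_name, threshold = thr, m_snps = r$m_snps,
        alpha = r$alpha_hat, se = r$se_alpha, z = r$z, chi2 = r$chi2,
        p = r$pval, pseudo_r2 = r$pseudo_r2, stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set = character(0), threshold = numeric(0),
               m_snps = integer(0), alpha = numeric(0), se = numeric(0),
               z = numeric(0), chi2 = numeric(0), p = numeric(0),
               pseudo_r2 = numeric(0))
  if (length(skipped)) {
    message(length(skipped), " empty instrument(s) skipped: ",
            paste(skipped, collapse = ", "))
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
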