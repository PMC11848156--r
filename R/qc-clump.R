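#' Filter variants on minor allele frequency and imputation quality
#'
#' Excludes variants with MAF below `maf_min` or INFO below `info_min`.
#' Exclusion is strict: a variant exactly at a threshold is retained.
#' Counts of each rejection reason are recorded in
#' `attr(result, "filter_log")`.
#'
#' @param ss a [sumstats] object.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param info_min minimum imputation INFO score (default 0.9).
#' @return The filtered `sumstats`.
#' @export
filter_variants <- function(ss, maf_min = 0.01, info_min = 0.9) {
  stopifnot(inherits(ss, "sumstats"),
            maf_min > 0, maf_min <= 0.5, info_min > 0, info_min <= 1.2)
  v <- ss$variants
  low_maf <- v$maf < maf_min
  low_info <- v$info < info_min
  keep <- !low_maf & !low_info
  out <- ss
  out$variants <- v[keep, , drop = FALSE]
  rownames(out$variants) <- NULL
  attr(out, "filter_log") <- c(
    n_in = nrow(v), n_out = sum(keep),
    removed_low_maf = sum(low_maf),
    removed_low_info = sum(low_info & !low_maf)
  )
  out
}

#' Remove variants falling inside fixed genomic regions
#'
#' A variant is removed when its chromosome matches a region's and its
#' position lies in \[start_bp, end_bp\], inclusive at both boundaries.
#' Used to strip the APOE and MHC loci before score construction so that
#' associations are not driven by single high-effect loci or complex LD.
#'
#' @param ss a [sumstats] object.
#' @param regions data.frame with columns `chrom`, `start_bp`, `end_bp`
#'   (and optionally `label`); default [default_excluded_regions()].
#' @return The filtered `sumstats`, with per-region removal counts in
#'   `attr(result, "region_log")`.
#' @export
exclude_regions <- function(ss, regions = default_excluded_regions()) {
  stopifnot(inherits(ss, "sumstats"))
  v <- ss$variants
  drop <- rep(FALSE, nrow(v))
  counts <- integer(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    hit <- v$chrom == regions$chrom[i] &
      v$pos >= regions$start_bp[i] & v$pos <= regions$end_bp[i]
    counts[i] <- sum(hit)
    drop <- drop | hit
  }
  names(counts) <- if ("label" %in% names(regions)) regions$label else
    paste0(regions$chrom, ":", regions$start_bp, "-", regions$end_bp)
  out <- ss
  out$variants <- v[!drop, , drop = FALSE]
  rownames(out$variants) <- NULL
  attr(out, "region_log") <- counts
  out
}

#' Squared dosage correlation between two variants in the LD reference
#'
#' The composite-genotype measure of linkage disequilibrium: the squared
#' Pearson correlation of the two variants' dosage vectors. A
#' zero-variance dosage vector yields r^2 = 0 with a warning.
#'
#' @param snp_a,snp_b snp_ids present in the reference.
#' @param ld_ref a [dosage_ref].
#' @return r^2 in \[0, 1\].
#' @export
compute_r2 <- function(snp_a, snp_b, ld_ref) {
  d <- ld_ref$dosages
  for (s in c(snp_a, snp_b)) {
    if (!s %in% rownames(d)) stop("SNP absent from LD reference: ", s)
  }
  a <- d[snp_a, ]
  b <- d[snp_b, ]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero-variance dosage; r^2 defined as 0")
    return(0)
  }
  stats::cor(a, b)^2
}

# centered+scaled LD rows for fast r2 against many candidates; rows with
# zero variance become all-zero (r2 = 0 against everything)
scale_ld_rows <- function(dosages) {
  mu <- rowMeans(dosages)
  x <- dosages - mu
  ss <- sqrt(rowSums(x^2))
  zero <- ss == 0
  ss[zero] <- 1
  x <- x / ss
  x[zero, ] <- 0
  x
}

#' Greedy LD clumping of an exposure GWAS
#'
#' Reduces the summary statistics to an approximately uncorrelated index
#' SNP pool: repeatedly take the unprocessed SNP with the smallest
#' exposure p-value as an index SNP and remove every unprocessed SNP on
#' the same chromosome within +/- `window_kb` x 1000 bp whose r^2 with
#' the index (in the LD reference) exceeds `r2_max`. Ties on p-value are
#' broken by smaller (chrom, pos), so the result is independent of input
#' row order. SNPs absent from the LD reference are, by default, treated
#' as uncorrelated with everything and retained with a warning
#' (`missing_ld = "drop"` removes them instead).
#'
#' @param ss a filtered [sumstats] object.
#' @param ld_ref a [dosage_ref] covering (most of) the SNPs.
#' @param window_kb clump window half-width in kb (default 10000, i.e.
#'   +/-10 Mb).
#' @param r2_max maximum tolerated r^2 between retained SNPs within the
#'   window (default 0.001).
#' @param missing_ld policy for SNPs missing from the reference.
#' @return A list of class `clump_result`: `retained` (ordered snp_ids of
#'   index SNPs), `removed` (named character: removed snp_id -> index
#'   snp_id that absorbed it), `params`.
#' @export
clump <- function(ss, ld_ref, window_kb = 10000, r2_max = 0.001,
                  missing_ld = c("keep", "drop")) {
  missing_ld <- match.arg(missing_ld)
  if (window_kb <= 0) stop("window_kb must be positive")
  if (r2_max < 0 || r2_max >= 1) stop("r2_max must lie in [0, 1)")
  v <- ss$variants
  window_bp <- as.numeric(window_kb) * 1000

  in_ref <- v$snp_id %in% rownames(ld_ref$dosages)
  dropped_missing <- character(0)
  if (any(!in_ref)) {
    if (missing_ld == "drop") {
      dropped_missing <- v$snp_id[!in_ref]
      v <- v[in_ref, , drop = FALSE]
    } else {
      warning(sum(!in_ref),
              " SNP(s) absent from LD reference treated as uncorrelated")
    }
  }

  # deterministic processing order: p ascending, then (chrom, pos)
  ord <- order(v$pval, v$chrom, v$pos)
  v <- v[ord, , drop = FALSE]
  n <- nrow(v)
  retained <- character(0)
  removed <- character(0)
  removed_by <- character(0)
  if (n) {
    have_ld <- v$snp_id %in% rownames(ld_ref$dosages)
    x <- scale_ld_rows(ld_ref$dosages[v$snp_id[have_ld], , drop = FALSE])
    ld_row <- match(v$snp_id, rownames(x))
    alive <- rep(TRUE, n)
    for (i in seq_len(n)) {
      if (!alive[i]) next
      alive[i] <- FALSE
      retained <- c(retained, v$snp_id[i])
      cand <- which(alive & v$chrom == v$chrom[i] &
                      abs(v$pos - v$pos[i]) <= window_bp)
      if (!length(cand) || is.na(ld_row[i])) next
      cand <- cand[!is.na(ld_row[cand])]
      if (!length(cand)) next
      r2 <- as.vector(x[ld_row[cand], , drop = FALSE] %*% x[ld_row[i], ])^2
      kill <- cand[r2 > r2_max]
      if (length(kill)) {
        alive[kill] <- FALSE
        removed <- c(removed, v$snp_id[kill])
        removed_by <- c(removed_by, rep(v$snp_id[i], length(kill)))
      }
    }
  }
  names(removed_by) <- removed
  structure(
    list(retained = retained, removed = removed_by,
         dropped_missing_ld = dropped_missing,
         params = list(window_kb = window_kb, r2_max = r2_max,
                       missing_ld = missing_ld)),
    class = "clump_result"
  )
}

#' @export
print.clump_result <- function(x, ...) {
  cat(sprintf("<clump_result> retained=%d removed=%d (window=%d kb, r2<=%g)\n",
              length(x$retained), length(x$removed),
              x$params$window_kb, x$params$r2_max))
  invisible(x)
}

#' Restrict summary statistics to a set of SNPs
#' @param ss a [sumstats] object.
#' @param snp_ids character vector of snp_ids to keep.
#' @return The subset `sumstats`.
#' @export
subset_sumstats <- function(ss, snp_ids) {
  out <- ss
  out$variants <- ss$variants[ss$variants$snp_id %in% snp_ids, , drop = FALSE]
  rownames(out$variants) <- NULL
  out
}
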