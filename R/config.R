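#' Default run configuration
#'
#' Assembles the configuration object that parameterizes every pipeline
#' stage: variant QC thresholds, clumping parameters, fixed excluded
#' regions, SNP-to-gene windows, the p-value threshold scan, permutation
#' size, and the family-wise error rate.
#'
#' Defaults encode the standard analysis settings: variants with
#' MAF < 0.01 or INFO < 0.9 are excluded; clumping uses a +/-10 Mb window
#' at r^2 <= 0.001; the APOE (chr19:44.5-46 Mb) and MHC (chr6:26-34 Mb)
#' regions are removed before score construction; SNPs are assigned to
#' protein-coding genes within 2 kb upstream / 0.5 kb downstream; scores
#' are scanned over three progressive exposure p-value thresholds; the
#' permutation null uses 1000 size-matched SNP sets.
#'
#' @param ... named overrides for any default field.
#'
#' @return A list of class `prs_config` with fields `maf_min`, `info_min`,
#'   `clump_window_kb`, `clump_r2_max`, `excluded_regions`, `upstream_bp`,
#'   `downstream_bp`, `p_thresholds`, `n_perm`, `rng_seed`, `fwe_alpha`,
#'   plus policy switches (`missing_ld_policy`, `palindromic_policy`,
#'   `fwe_method`, `pseudo_r2_form`, `strand_aware_windows`,
#'   `marker_bin_quantile`, `multi_set_snp_policy`).
#' @export
#' @examples
#' cfg <- prs_config(n_perm = 200, rng_seed = 42)
#' cfg$clump_window_kb
prs_config <- function(...) {
  cfg <- list(
    maf_min          = 0.01,
    info_min         = 0.9,
    clump_window_kb  = 10000,
    clump_r2_max     = 0.001,
    excluded_regions = default_excluded_regions(),
    upstream_bp      = 2000,
    downstream_bp    = 500,
    p_thresholds     = c(0.01, 0.5, 1.0),
    n_perm           = 1000,
    rng_seed         = 1L,
    fwe_alpha        = 0.05,
    frac_discovery   = 2 / 3,
    # policy switches
    missing_ld_policy    = c("keep", "drop"),
    palindromic_policy   = c("keep", "drop"),
    fwe_method           = c("bonferroni", "holm"),
    pseudo_r2_form       = c("lrt", "first_order"),
    strand_aware_windows = TRUE,
    marker_bin_quantile  = 0.9,
    marker_fdr_alpha     = 0.05,
    multi_set_snp_policy = c("both", "first"),
    replication_p        = 0.05
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  for (f in c("missing_ld_policy", "palindromic_policy", "fwe_method",
              "pseudo_r2_form", "multi_set_snp_policy")) {
    cfg[[f]] <- match.arg(cfg[[f]], c(cfg[[f]][1L], cfg[[f]][-1L]))
  }
  validate_config(cfg)
  structure(cfg, class = "prs_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$maf_min > 0, cfg$maf_min <= 0.5,
    cfg$info_min > 0, cfg$info_min <= 1.2,
    cfg$clump_window_kb > 0,
    cfg$clump_r2_max >= 0, cfg$clump_r2_max < 1,
    cfg$upstream_bp >= 0, cfg$downstream_bp >= 0,
    all(cfg$p_thresholds > 0), all(cfg$p_thresholds <= 1),
    !is.unsorted(cfg$p_thresholds, strictly = TRUE),
    cfg$n_perm >= 1,
    cfg$fwe_alpha > 0, cfg$fwe_alpha < 1,
    cfg$frac_discovery > 0, cfg$frac_discovery < 1
  )
  invisible(cfg)
}

#' Regions excluded from score construction by default
#'
#' The APOE locus (chr19:44,500-46,000 kb) and the MHC
#' (chr6:26,000-34,000 kb). Kilobase boundaries are interpreted as
#' kb x 1000 bp, inclusive at both ends.
#'
#' @return data.frame with columns `chrom`, `start_bp`, `end_bp`, `label`.
#' @export
default_excluded_regions <- function() {
  data.frame(
    chrom    = c("19", "6"),
    start_bp = c(44500000L, 26000000L),
    end_bp   = c(46000000L, 34000000L),
    label    = c("APOE", "MHC"),
    stringsAsFactors = FALSE
  )
}

#' Read a run configuration from a YAML file
#'
#' Keys present in the file override the corresponding defaults from
#' [prs_config()]; `excluded_regions`, if given, must be a list of
#' records with `chrom`, `start_bp`, `end_bp`, `label`.
#'
#' @param path YAML file.
#' @return A `prs_config` object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$excluded_regions)) {
    raw$excluded_regions <- do.call(
      rbind,
      lapply(raw$excluded_regions, function(r) {
        data.frame(chrom = as.character(r$chrom),
                   start_bp = as.integer(r$start_bp),
                   end_bp = as.integer(r$end_bp),
                   label = as.character(r$label %||% ""),
                   stringsAsFactors = FALSE)
      })
    )
  }
  do.call(prs_config, raw)
}

#' Write a run configuration to YAML
#' @param cfg A `prs_config` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$excluded_regions <- lapply(
    seq_len(nrow(cfg$excluded_regions)),
    function(i) as.list(cfg$excluded_regions[i, , drop = FALSE])
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible per-stage RNG seed
#'
#' Every source of randomness in the pipeline draws its seed from the
#' single run seed through a named substream, so each stage is
#' independently reproducible regardless of what ran before it.
#'
#' @param seed integer master seed.
#' @param stage character stage name (e.g. "genotypes", "permutation").
#' @return An integer seed in \[0, 2^31).
#' @export
rng_substream <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(stage)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}
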