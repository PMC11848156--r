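#' Map SNPs to proximal protein-coding genes
#'
#' A SNP maps to a gene when its position lies within the gene body
#' extended by an asymmetric window: `upstream_bp` beyond the 5' end and
#' `downstream_bp` beyond the 3' end. With strand-aware windows (the
#' default) a "+" gene's window is \[start - upstream, end + downstream\]
#' and a "-" gene's is \[start - downstream, end + upstream\]; with
#' `strand_aware = FALSE` every gene uses the "+" arrangement. Only
#' protein-coding genes are eligible, and a SNP may map to several genes
#' where windows overlap. SNPs mapping to no gene are absent from the
#' result (and thereby dropped from score construction).
#'
#' @param snps data.frame of variant metadata with `snp_id`, `chrom`,
#'   `pos` (e.g. the `variants` table of a [sumstats]).
#' @param genes gene annotation data.frame as from
#'   [read_gene_annotation].
#' @param upstream_bp,downstream_bp window sizes in bp (defaults 2000
#'   and 500).
#' @param strand_aware treat the windows as 5'/3'-relative (default).
#' @return data.frame `snp_id`, `gene_id`, `distance` (0 when inside the
#'   gene body, otherwise bp to the nearer gene edge), one row per
#'   (SNP, gene) pair.
#' @export
map_snps_to_genes <- function(snps, genes, upstream_bp = 2000,
                              downstream_bp = 500, strand_aware = TRUE) {
  stopifnot(upstream_bp >= 0, downstream_bp >= 0)
  g <- genes[genes$protein_coding, , drop = FALSE]
  if (!nrow(g) || !nrow(snps)) {
    return(data.frame(snp_id = character(0), gene_id = character(0),
                      distance = integer(0)))
  }
  minus <- strand_aware & g$strand == "-"
  win_start <- ifelse(minus, g$start - downstream_bp, g$start - upstream_bp)
  win_end   <- ifelse(minus, g$end + upstream_bp, g$end + downstream_bp)

  out <- vector("list", nrow(g))
  for (j in seq_len(nrow(g))) {
    hit <- snps$chrom == g$chrom[j] &
      snps$pos >= win_start[j] & snps$pos <= win_end[j]
    if (!any(hit)) next
    pos <- snps$pos[hit]
    dist <- pmax(0L, pmax(g$start[j] - pos, pos - g$end[j]))
    out[[j]] <- data.frame(snp_id = snps$snp_id[hit], gene_id = g$gene_id[j],
                           distance = as.integer(dist),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(snp_id = character(0), gene_id = character(0),
                      distance = integer(0))
  }
  rownames(res) <- NULL
  res
}

#' Collapse the SNP-gene map to one SNP per gene
#'
#' For each gene with more than one mapped SNP, retain exactly the SNP
#' with the smallest exposure p-value (ties broken by smaller
#' (chrom, pos)). SNPs that still map to more than one gene after this
#' step are assigned to their nearest gene by distance to the gene body
#' (ties broken by the gene with the smaller start). The result is a
#' one-to-one SNP-gene correspondence.
#'
#' @param snp_gene_map data.frame from [map_snps_to_genes].
#' @param exposure the exposure [sumstats] (must contain every mapped
#'   SNP).
#' @param genes gene annotation (used for the nearest-gene tie-break).
#' @return data.frame `snp_id`, `gene_id`, `distance` with `gene_id`
#'   unique and `snp_id` unique.
#' @export
dedup_one_snp_per_gene <- function(snp_gene_map, exposure, genes) {
  m <- snp_gene_map
  if (!nrow(m)) return(m)
  v <- exposure$variants
  idx <- match(m$snp_id, v$snp_id)
  if (anyNA(idx)) {
    stop("mapped SNP missing from exposure summary statistics: ",
         m$snp_id[is.na(idx)][1L])
  }
  m$pval <- v$pval[idx]
  m$chrom <- v$chrom[idx]
  m$pos <- v$pos[idx]
  m$gene_start <- genes$start[match(m$gene_id, genes$gene_id)]

  # step 1: per gene keep the smallest-p SNP (tie: smaller chrom, pos)
  ord <- order(m$gene_id, m$pval, m$chrom, m$pos)
  m <- m[ord, , drop = FALSE]
  m <- m[!duplicated(m$gene_id), , drop = FALSE]

  # step 2: residual multi-gene SNPs go to the nearest gene (tie: smaller
  # gene start)
  ord <- order(m$snp_id, m$distance, m$gene_start)
  m <- m[ord, , drop = FALSE]
  m <- m[!duplicated(m$snp_id), , drop = FALSE]

  m <- m[order(m$chrom, m$pos), c("snp_id", "gene_id", "distance")]
  rownames(m) <- NULL
  m
}

#' Derive cell-type marker gene sets from a mean-expression table
#'
#' Marker genes are those over-expressed in a cell type relative to
#' background. Over-expression is scored as a log2 fold change of the
#' cell type's mean expression against the per-gene background mean
#' (with a pseudocount), and significance by the cumulative (upper-tail)
#' hypergeometric test on the count-scale table: for gene g in cell type
#' c, the probability of the observed (or more) expression units of g
#' falling in c when g's total units are distributed over cell types in
#' proportion to their overall depth. p-values are Benjamini-Hochberg
#' corrected across genes within each cell type. A gene is a marker of a
#' cell type when lfc > 0, FDR < `fdr_alpha`, and (optionally) the gene
#' sits in the cell type's top-expression bin.
#'
#' @param expr numeric gene x cell-type matrix of nonnegative
#'   count-scale mean expression (rownames = gene ids).
#' @param background optional per-gene background means; defaults to the
#'   row mean across cell types.
#' @param fdr_alpha FDR threshold for marker membership (default 0.05).
#' @param bin_quantile restrict markers to genes at or above this
#'   expression quantile within the cell type (default 0.9, the top
#'   decile); `NULL` disables the bin filter.
#' @return A list with `sets` (named list of marker gene ids, class
#'   `cell_type_sets`) and `records` (data.frame `gene_id`, `cell_type`,
#'   `lfc`, `p_hyper`, `fdr`).
#' @export
score_marker_enrichment <- function(expr, background = NULL,
                                    fdr_alpha = 0.05, bin_quantile = 0.9) {
  expr <- as.matrix(expr)
  if (any(expr < 0)) stop("expression must be nonnegative")
  zero_rows <- rowSums(expr) == 0
  if (any(zero_rows)) {
    warning(sum(zero_rows), " all-zero expression row(s) skipped")
    expr <- expr[!zero_rows, , drop = FALSE]
  }
  if (is.null(background)) background <- rowMeans(expr)
  eps <- 1e-9 * mean(expr)
  if (eps == 0) eps <- 1e-9
  lfc <- log2((expr + eps) / (background + eps))

  # hypergeometric on rounded expression units
  units <- round(expr)
  gene_tot <- rowSums(units)
  type_tot <- colSums(units)
  total <- sum(units)
  p_hyper <- matrix(1, nrow(units), ncol(units),
                    dimnames = dimnames(units))
  for (j in seq_len(ncol(units))) {
    p_hyper[, j] <- stats::phyper(units[, j] - 1, gene_tot,
                                  total - gene_tot, type_tot[j],
                                  lower.tail = FALSE)
  }
  fdr <- apply(p_hyper, 2, stats::p.adjust, method = "BH")

  in_bin <- matrix(TRUE, nrow(expr), ncol(expr))
  if (!is.null(bin_quantile)) {
    for (j in seq_len(ncol(expr))) {
      cut <- stats::quantile(expr[, j], bin_quantile, type = 1)
      in_bin[, j] <- expr[, j] >= cut
    }
  }

  records <- data.frame(
    gene_id = rep(rownames(expr), ncol(expr)),
    cell_type = rep(colnames(expr), each = nrow(expr)),
    lfc = as.vector(lfc),
    p_hyper = as.vector(p_hyper),
    fdr = as.vector(fdr),
    stringsAsFactors = FALSE
  )
  marker <- as.vector(lfc > 0 & fdr < fdr_alpha & in_bin)
  sets <- split(records$gene_id[marker], records$cell_type[marker])
  empty_types <- setdiff(colnames(expr), names(sets))
  sets[empty_types] <- list(character(0))
  sets <- sets[colnames(expr)]
  list(sets = structure(sets, class = "cell_type_sets"), records = records)
}

#' Assemble per-cell-type SNP sets
#'
#' A cell type's SNP set contains the SNP of every gene in its marker
#' set under the deduplicated one-SNP-per-gene map. A SNP whose gene is
#' a shared marker appears in several sets (`multi_set = "both"`, the
#' default); `"first"` assigns it only to the first set listing its
#' gene. Cell types whose SNP set is empty are retained with cardinality
#' 0 and flagged in `attr(result, "empty_sets")`; downstream association
#' skips them with a log entry.
#'
#' @param snp_gene_map deduplicated map from [dedup_one_snp_per_gene].
#' @param cell_sets named list of marker gene sets.
#' @param multi_set policy for SNPs whose gene belongs to several sets.
#' @return Named list mapping cell type -> character vector of snp_ids.
#' @export
build_cell_snp_sets <- function(snp_gene_map, cell_sets,
                                multi_set = c("both", "first")) {
  multi_set <- match.arg(multi_set)
  used <- character(0)
  out <- lapply(cell_sets, function(genes) {
    s <- snp_gene_map$snp_id[snp_gene_map$gene_id %in% genes]
    if (multi_set == "first") {
      s <- setdiff(s, used)
      used <<- c(used, s)
    }
    s
  })
  names(out) <- names(cell_sets)
  empty <- names(out)[lengths(out) == 0L]
  if (length(empty)) {
    message("cell type(s) with empty SNP set flagged: ",
            paste(empty, collapse = ", "))
  }
  attr(out, "empty_sets") <- empty
  out
}
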