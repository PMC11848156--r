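#' Construct a GWAS summary-statistics object
#'
#' The central container of the pipeline: a validated per-variant
#' association table plus trait metadata. Variants are stored sorted by
#' (chrom, pos) regardless of input order. Rows violating the per-variant
#' invariants (se > 0, p in (0,1], MAF in (0,0.5], INFO in (0,1.2],
#' distinct single-base alleles) are rejected with counts recorded in
#' `attr(x, "rejections")`.
#'
#' @param variants data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `allele_effect` (the coded allele whose dose the beta refers to),
#'   `allele_other`, `beta`, `se`, `pval`, `maf`, `info`, and optionally
#'   `n` (per-variant sample size).
#' @param trait character trait name.
#' @param n_total integer GWAS sample size.
#' @param validate reject invalid rows (default TRUE).
#' @return An object of class `sumstats`: a list with `trait`, `n_total`,
#'   `variants`.
#' @export
sumstats <- function(variants, trait = "trait", n_total = NA_integer_,
                     validate = TRUE) {
  req <- c("snp_id", "chrom", "pos", "allele_effect", "allele_other",
           "beta", "se", "pval", "maf", "info")
  missing_cols <- setdiff(req, names(variants))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"n" %in% names(variants)) variants$n <- NA_integer_
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  variants$snp_id <- as.character(variants$snp_id)
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  for (col in c("beta", "se", "pval", "maf", "info")) {
    variants[[col]] <- as.numeric(variants[[col]])
  }

  rejections <- c(bad_se = 0L, bad_pval = 0L, bad_maf = 0L, bad_info = 0L,
                  bad_alleles = 0L)
  if (validate && nrow(variants)) {
    ok_se   <- is.finite(variants$se) & variants$se > 0
    ok_p    <- is.finite(variants$pval) & variants$pval > 0 & variants$pval <= 1
    ok_maf  <- is.finite(variants$maf) & variants$maf > 0 & variants$maf <= 0.5
    ok_info <- is.finite(variants$info) & variants$info > 0 & variants$info <= 1.2
    ok_al   <- variants$allele_effect != variants$allele_other &
      variants$allele_effect %in% c("A", "C", "G", "T") &
      variants$allele_other %in% c("A", "C", "G", "T")
    rejections <- c(
      bad_se = sum(!ok_se), bad_pval = sum(ok_se & !ok_p),
      bad_maf = sum(ok_se & ok_p & !ok_maf),
      bad_info = sum(ok_se & ok_p & ok_maf & !ok_info),
      bad_alleles = sum(ok_se & ok_p & ok_maf & ok_info & !ok_al)
    )
    keep <- ok_se & ok_p & ok_maf & ok_info & ok_al
    if (any(!keep)) {
      message(sum(!keep), " variant(s) rejected during validation (",
              paste(names(rejections)[rejections > 0L], "=",
                    rejections[rejections > 0L], collapse = ", "), ")")
    }
    variants <- variants[keep, , drop = FALSE]
  }

  if (anyDuplicated(variants$snp_id)) {
    stop("duplicate snp_id in summary statistics: ",
         variants$snp_id[duplicated(variants$snp_id)][1L])
  }
  key <- paste(variants$chrom, variants$pos)
  if (anyDuplicated(key)) {
    stop("duplicate (chrom,pos) in summary statistics: ",
         key[duplicated(key)][1L])
  }
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL

  structure(
    list(trait = trait, n_total = as.integer(n_total), variants = variants),
    rejections = rejections,
    class = "sumstats"
  )
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> trait=%s  n_total=%s  variants=%d\n",
              x$trait, format(x$n_total), nrow(x$variants)))
  invisible(x)
}

#' Number of variants in a summary-statistics object
#' @param ss a `sumstats` object.
#' @return integer count.
#' @export
n_variants <- function(ss) nrow(ss$variants)

# canonical column names of the tab-delimited interchange format
sumstats_canonical_cols <- c(
  snp_id = "SNP", chrom = "CHR", pos = "BP", allele_effect = "A1",
  allele_other = "A2", beta = "BETA", se = "SE", pval = "P",
  maf = "MAF", info = "INFO", n = "N"
)

#' Read GWAS summary statistics from a delimited file
#'
#' Expects a tab- or whitespace-delimited file with a header row. The
#' canonical column names are SNP, CHR, BP, A1 (coded allele), A2, BETA,
#' SE, P, MAF, INFO and optionally N; files with other headers are
#' adapted through `dialect`, a named mapping from canonical to actual
#' column names. Rows failing the per-variant invariants are rejected
#' with counts logged; a missing mandatory column or a duplicated snp_id
#' is an error. Unknown extra columns are preserved.
#'
#' @param path input file.
#' @param dialect named character vector, e.g.
#'   `c(SNP = "rsid", BETA = "b")`; unmentioned columns keep their
#'   canonical names.
#' @param trait trait label (default: file base name).
#' @param n_total GWAS sample size; defaults to `max(N)` when an N column
#'   is present.
#' @return A [sumstats] object.
#' @export
read_sumstats <- function(path, dialect = NULL, trait = NULL, n_total = NULL) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = list(character = 1L))
  file_cols <- sumstats_canonical_cols
  if (!is.null(dialect)) {
    key <- match(names(dialect), sumstats_canonical_cols)
    if (anyNA(key)) {
      stop("dialect maps unknown canonical column(s): ",
           paste(names(dialect)[is.na(key)], collapse = ", "))
    }
    file_cols[key] <- dialect
  }
  mandatory <- setdiff(names(file_cols), "n")
  for (canon in mandatory) {
    if (!file_cols[[canon]] %in% names(dt)) {
      stop("missing mandatory column: ", file_cols[[canon]],
           " (canonical ", sumstats_canonical_cols[[canon]], ")")
    }
  }
  present <- names(file_cols)[file_cols %in% names(dt)]
  variants <- dt[, file_cols[present], drop = FALSE]
  names(variants) <- present
  extra <- setdiff(names(dt), file_cols)
  if (length(extra)) variants[extra] <- dt[extra]
  if (is.null(trait)) trait <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(n_total)) {
    nn <- if ("n" %in% present) variants$n[!is.na(variants$n)] else integer(0)
    n_total <- if (length(nn)) max(nn) else NA_integer_
  }
  sumstats(variants, trait = trait, n_total = n_total)
}

#' Write GWAS summary statistics to a tab-delimited file
#'
#' Inverse of [read_sumstats] under the canonical column names;
#' round-trips all record fields (extra columns included).
#'
#' @param ss a `sumstats` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  v <- ss$variants
  canon <- names(sumstats_canonical_cols)
  keep <- canon[canon %in% names(v)]
  out <- v[, c(keep, setdiff(names(v), canon)), drop = FALSE]
  names(out)[seq_along(keep)] <- sumstats_canonical_cols[keep]
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read named gene sets from a GMT file
#'
#' One set per line: name TAB description TAB member gene ids. Duplicate
#' set names and empty sets are load errors.
#'
#' @param path GMT file.
#' @return Named list of character vectors of gene ids (class
#'   `cell_type_sets`).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nms)) {
    stop("duplicate gene-set name: ", nms[duplicated(nms)][1L])
  }
  sets <- lapply(fields, function(f) {
    genes <- unique(f[-(1:2)])
    genes[nzchar(genes)]
  })
  names(sets) <- nms
  empty <- lengths(sets) == 0L
  if (any(empty)) stop("empty gene set: ", nms[empty][1L])
  structure(sets, class = "cell_type_sets")
}

#' Write named gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene annotations from a BED-like file
#'
#' Six tab-delimited columns: chrom, start, end, gene_id, protein-coding
#' flag (0/1), strand (+/-). With `zero_based = TRUE` (the BED
#' convention, default) starts are 0-based half-open and are converted to
#' the internal 1-based inclusive convention on read.
#'
#' @param path input file.
#' @param zero_based whether starts follow the BED 0-based half-open
#'   convention.
#' @return data.frame of gene records (`gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `protein_coding`) sorted by (chrom, start).
#' @export
read_gene_annotation <- function(path, zero_based = TRUE) {
  dt <- data.table::fread(path, header = FALSE, data.table = FALSE,
                          col.names = c("chrom", "start", "end", "gene_id",
                                        "protein_coding", "strand"),
                          colClasses = list(character = c(1L, 4L, 6L)))
  genes <- data.frame(
    gene_id = dt$gene_id,
    chrom = dt$chrom,
    start = as.integer(dt$start) + if (zero_based) 1L else 0L,
    end = as.integer(dt$end),
    strand = dt$strand,
    protein_coding = as.logical(as.integer(dt$protein_coding)),
    stringsAsFactors = FALSE
  )
  bad <- genes$start > genes$end
  if (any(bad)) {
    stop("gene record with start > end: ", genes$gene_id[bad][1L])
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  genes
}

#' Write gene annotations to a BED-like file
#' @param genes data.frame as returned by [read_gene_annotation].
#' @param path output file.
#' @param zero_based write BED 0-based half-open starts (default TRUE).
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path, zero_based = TRUE) {
  out <- data.frame(
    chrom = genes$chrom,
    start = genes$start - if (zero_based) 1L else 0L,
    end = genes$end,
    gene_id = genes$gene_id,
    protein_coding = as.integer(genes$protein_coding),
    strand = genes$strand
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a genotype-dosage reference panel
#'
#' @param dosages numeric matrix, rows = variants (rownames = snp_id),
#'   columns = reference individuals, entries in \[0, 2\] counting doses
#'   of the coded allele.
#' @param variants optional data.frame of per-variant metadata
#'   (`snp_id`, `chrom`, `pos`, `allele_effect`, ...) row-aligned to the
#'   matrix.
#' @return Object of class `dosage_ref`.
#' @export
dosage_ref <- function(dosages, variants = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages))) stop("dosage matrix must have snp_id rownames")
  rng <- range(dosages)
  if (rng[1L] < 0 || rng[2L] > 2) {
    stop("dosage entries must lie in [0, 2]; found range [",
         rng[1L], ", ", rng[2L], "]")
  }
  if (anyDuplicated(rownames(dosages))) stop("duplicate snp_id in dosage matrix")
  if (!is.null(variants)) {
    stopifnot(identical(as.character(variants$snp_id), rownames(dosages)))
  }
  structure(list(dosages = dosages, variants = variants), class = "dosage_ref")
}

#' @export
print.dosage_ref <- function(x, ...) {
  cat(sprintf("<dosage_ref> %d variants x %d individuals\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Read a genotype-dosage reference panel
#'
#' Two formats: a plain TSV matrix (first column snp_id, remaining
#' columns one per reference individual, entries in \[0, 2\]), or an
#' uncompressed VCF whose GT fields are converted to alternate-allele
#' dose (0/0 -> 0, 0/1 -> 1, 1/1 -> 2); the ALT allele is taken as the
#' coded allele. VCF parsing is delegated to the vcfR package.
#'
#' @param path input file.
#' @param format "tsv", "vcf", or "auto" (by file extension).
#' @return A [dosage_ref].
#' @export
read_dosage_matrix <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  }
  if (format == "vcf") {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("reading VCF dosages requires the vcfR package")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    dose <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1L]]) > 0L)
    })
    fix <- vcfR::getFIX(v)
    variants <- data.frame(
      snp_id = fix[, "ID"], chrom = as.character(fix[, "CHROM"]),
      pos = as.integer(fix[, "POS"]),
      allele_effect = fix[, "ALT"], allele_other = fix[, "REF"],
      stringsAsFactors = FALSE
    )
    rownames(dose) <- variants$snp_id
    return(dosage_ref(dose, variants))
  }
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = list(character = 1L))
  m <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- dt[[1L]]
  dosage_ref(m)
}

#' Write a dosage reference panel as a TSV matrix
#' @param ref a `dosage_ref`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dosage_matrix <- function(ref, path) {
  out <- data.frame(snp_id = rownames(ref$dosages), ref$dosages,
                    check.names = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
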