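#' Median-of-ratios size factors
#'
#' Estimates one positive scale factor per sample as the median, over a
#' reference gene set, of the ratio of the sample's count to the gene's
#' geometric mean across samples. Factors are rescaled to geometric mean 1 so
#' normalized counts live on a common scale. The reference set defaults to
#' all genes with no zero count in any sample; no pseudo-reference fallback
#' is applied when that set is empty — the estimator fails explicitly.
#'
#' @param counts Non-negative integer gene x sample matrix.
#' @param reference_genes Optional character vector of gene ids to use as the
#'   reference; must be free of zero counts.
#' @return Object of class `xy_size_factors`: list with `factors` (named
#'   positive numeric, geometric mean 1) and `reference_genes`.
#' @examples
#' m <- matrix(c(10, 20, 5, 20, 40, 10), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("a", "b")))
#' size_factors(m)$factors  # b is 2x a
#' @export
size_factors <- function(counts, reference_genes = NULL) {
  stopifnot_matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  no_zero <- rownames(counts)[rowSums(counts == 0) == 0]
  if (is.null(reference_genes)) {
    reference_genes <- no_zero
  } else {
    bad <- setdiff(reference_genes, no_zero)
    if (length(bad)) {
      stop(sprintf(
        "reference genes with zero counts are not allowed: %s",
        paste(head(bad, 5), collapse = ", ")), call. = FALSE)
    }
  }
  if (length(reference_genes) == 0) {
    stop(paste("no gene is free of zero counts across all samples;",
               "median-of-ratios size factors are undefined and no",
               "pseudo-reference fallback is applied"), call. = FALSE)
  }
  lc <- log(counts[reference_genes, , drop = FALSE])
  log_geo <- rowMeans(lc)
  raw <- apply(lc, 2, function(col) exp(median(col - log_geo)))
  f <- raw / exp(mean(log(raw)))
  structure(list(factors = f, reference_genes = reference_genes),
            class = "xy_size_factors")
}

as_size_factor_vector <- function(sf, counts) {
  f <- if (inherits(sf, "xy_size_factors")) sf$factors else sf
  if (length(f) != ncol(counts) || any(f <= 0)) {
    stop("size factors must be positive, one per sample", call. = FALSE)
  }
  f
}

#' Transcripts per million
#'
#' Length-normalized within-sample expression:
#' `TPM_gj = 1e6 * (count_gj / length_g) / sum_g(count_gj / length_g)`.
#' Columns sum to one million.
#'
#' @param counts Gene x sample count matrix.
#' @param gene_lengths Positive effective lengths, named by gene or aligned
#'   to the rows of `counts`.
#' @return TPM matrix of the same shape.
#' @export
compute_tpm <- function(counts, gene_lengths) {
  stopifnot_matrix(counts)
  if (!is.null(names(gene_lengths)) && !is.null(rownames(counts))) {
    gene_lengths <- gene_lengths[rownames(counts)]
  }
  if (length(gene_lengths) != nrow(counts) || any(is.na(gene_lengths)) ||
      any(gene_lengths <= 0)) {
    stop("`gene_lengths` must be positive, one per gene", call. = FALSE)
  }
  rate <- counts / gene_lengths
  tot <- colSums(rate)
  zero <- which(tot == 0)
  if (length(zero)) {
    stop(sprintf("sample(s) with zero total expression: %s",
                 paste(colnames(counts)[zero] %||% zero, collapse = ", ")),
         call. = FALSE)
  }
  sweep(rate, 2, tot, "/") * 1e6
}

#' Expression filter on euploid female and male samples
#'
#' Keeps a gene if its median TPM reaches `min_tpm` in 46,XX samples or in
#' 46,XY samples (OR semantics): a gene expressed in only one euploid sex is
#' retained.
#'
#' @param tpm TPM matrix (genes x samples).
#' @param meta Sample metadata with columns `sample_id` and `karyotype`.
#' @param groups Two karyotype labels defining the reference groups.
#' @param min_tpm Median TPM threshold.
#' @return Character vector of retained gene ids.
#' @export
filter_expressed <- function(tpm, meta, groups = c("46,XX", "46,XY"),
                             min_tpm = 1) {
  stopifnot_matrix(tpm)
  missing <- setdiff(groups, meta$karyotype)
  if (length(missing)) {
    stop(sprintf("karyotype group(s) absent from metadata: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  keep <- rep(FALSE, nrow(tpm))
  for (grp in groups) {
    cols <- meta$sample_id[meta$karyotype == grp]
    med <- apply(tpm[, cols, drop = FALSE], 1, median)
    keep <- keep | (med >= min_tpm)
  }
  rownames(tpm)[keep]
}
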