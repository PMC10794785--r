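#' Assign peaks to genes by promoter-window intersection
#'
#' Flags a gene as bound when any peak intersects the window
#' `[TSS - half_width, TSS + half_width)` around its strand-aware
#' transcription start site (the annotated start for `+` strand genes, the
#' annotated end for `-` strand genes). All coordinates follow BED
#' semantics: 0-based, half-open; intersection requires at least one shared
#' base. Peaks on chromosomes absent from the annotation are counted in a
#' warning, not an error.
#'
#' @param peaks Data frame with `chrom`, `start`, `end` (0-based,
#'   half-open).
#' @param annotation Gene annotation with `gene_id`, `chrom` and either a
#'   `tss` column or `start`/`end`/`strand` to derive it.
#' @param half_width Window half-width in bases (1000 for promoter binding,
#'   30000 for hormone-receptor target definition).
#' @return Data frame `gene_id`, `bound` (logical), one row per annotated
#'   gene.
#' @export
assign_peaks_to_tss <- function(peaks, annotation, half_width) {
  if (half_width <= 0) stop("`half_width` must be positive", call. = FALSE)
  validate_peaks(peaks)
  ann <- annotation
  if (!"tss" %in% names(ann)) {
    stopifnot(all(c("start", "end", "strand") %in% names(ann)))
    ann$tss <- ifelse(ann$strand == "+", ann$start, ann$end)
  }
  stray <- setdiff(unique(peaks$chrom), unique(ann$chrom))
  if (length(stray)) {
    warning(sprintf(
      "%d peak chromosome(s) absent from the annotation: %s",
      length(stray), paste(stray, collapse = ", ")), call. = FALSE)
  }
  bound <- rep(FALSE, nrow(ann))
  if (nrow(peaks) > 0 && nrow(ann) > 0) {
    win_start <- pmax(ann$tss - half_width, 0)
    win_end <- ann$tss + half_width
    # half-open [s, e) -> 1-based closed [s + 1, e]
    windows <- GenomicRanges::GRanges(
      ann$chrom, IRanges::IRanges(win_start + 1, win_end))
    peaks_gr <- GenomicRanges::GRanges(
      peaks$chrom, IRanges::IRanges(peaks$start + 1, peaks$end))
    # seqlevel mismatches are already reported above as a counted warning
    hits <- suppressWarnings(GenomicRanges::findOverlaps(windows, peaks_gr))
    bound[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  data.frame(gene_id = ann$gene_id, bound = bound, stringsAsFactors = FALSE)
}

validate_peaks <- function(peaks) {
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks)))
  if (nrow(peaks) == 0) return(invisible(peaks))
  if (any(peaks$start < 0) || any(peaks$start >= peaks$end)) {
    stop("peaks must satisfy 0 <= start < end", call. = FALSE)
  }
  invisible(peaks)
}

#' Bound-and-responsive direct target genes
#'
#' A gene is a direct target of a factor when it is bound (peak within the
#' promoter window) AND significantly differentially expressed upon
#' perturbation of that factor (adjusted p < `alpha`). Bound genes with no
#' differential-expression record are not targets and are counted in a
#' warning.
#'
#' @param bound Output of [assign_peaks_to_tss()] (or a data frame with
#'   `gene_id`, `bound`).
#' @param de_results Data frame with `gene` and `padj` columns (e.g. an
#'   `effect_fit` restricted to one coefficient).
#' @param alpha Adjusted-p threshold.
#' @return Sorted character vector of target gene ids.
#' @export
direct_targets <- function(bound, de_results, alpha = 0.05) {
  stopifnot(all(c("gene_id", "bound") %in% names(bound)))
  bound_genes <- bound$gene_id[bound$bound]
  no_de <- setdiff(bound_genes, de_results$gene)
  if (length(no_de)) {
    warning(sprintf("%d bound gene(s) without a DE record; not targets",
                    length(no_de)), call. = FALSE)
  }
  de <- de_results[match(bound_genes, de_results$gene), ]
  sort(bound_genes[!is.na(de$padj) & de$padj < alpha])
}

#' Proportion of expressing cell lines with promoter binding
#'
#' For each gene, the number of cell lines with promoter binding divided by
#' the number of cell lines in which the gene is expressed. Genes expressed
#' in no line get a missing value (excluded downstream).
#'
#' @param bound_by_cell_line,expressed_by_cell_line Logical gene x
#'   cell-line matrices with identical dimnames.
#' @return Named numeric vector of proportions (NA where never expressed).
#' @export
binding_proportion <- function(bound_by_cell_line, expressed_by_cell_line) {
  if (!identical(dim(bound_by_cell_line), dim(expressed_by_cell_line)) ||
      !identical(dimnames(bound_by_cell_line),
                 dimnames(expressed_by_cell_line))) {
    stop("bound and expressed matrices must share dimnames", call. = FALSE)
  }
  n_expr <- rowSums(expressed_by_cell_line)
  prop <- rowSums(bound_by_cell_line & expressed_by_cell_line) / n_expr
  prop[n_expr == 0] <- NA_real_
  prop
}

#' Enrichment of a target set among responsive genes
#'
#' Hypergeometric overlap of a direct-target set with the positively and
#' negatively responsive gene sets, tested separately (transcriptional
#' activators are expected to enrich among positively responsive genes
#' only).
#'
#' @param target_set Direct target genes.
#' @param responsive_up,responsive_down Positively / negatively responsive
#'   gene sets.
#' @param universe Background (expressed) genes.
#' @param n_tests Bonferroni denominator passed to [overlap_test()].
#' @return List with elements `up` and `down`, each an `overlap_result`.
#' @export
target_enrichment <- function(target_set, responsive_up, responsive_down,
                              universe, n_tests = 1) {
  list(up = overlap_test(target_set, responsive_up, universe, n_tests),
       down = overlap_test(target_set, responsive_down, universe, n_tests))
}

#' Set difference of peak sets by exact interval identity
#'
#' Keeps intervals of `a` that do not appear (same chromosome, start and
#' end) in `b`; used to derive treatment-specific peaks from pre-computed
#' peak sets.
#'
#' @param a,b Peak data frames (`chrom`, `start`, `end`).
#' @return Rows of `a` absent from `b`.
#' @export
peak_setdiff <- function(a, b) {
  validate_peaks(a); validate_peaks(b)
  key <- function(p) paste(p$chrom, p$start, p$end)
  a[!key(a) %in% key(b), , drop = FALSE]
}
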