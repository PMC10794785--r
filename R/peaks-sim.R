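#' Generate peaks near the promoters of a chosen gene set
#'
#' Emits one interval per bound gene, centred on the gene's strand-aware TSS
#' plus a normal jitter truncated so the midpoint stays within
#' `+/- window` of the TSS. Coordinates are 0-based, half-open (BED
#' semantics). With `jitter_sd = 0` every peak midpoint sits exactly at the
#' TSS, and assignment at a matching half-width recovers exactly the bound
#' set.
#'
#' @param annotation Gene annotation (see [generate_annotation()]).
#' @param bound_gene_ids Genes to receive a peak; must all be annotated.
#' @param window Maximum midpoint-to-TSS distance in bases (> 0).
#' @param jitter_sd SD of midpoint jitter in bases.
#' @param peak_width Width of each peak in bases.
#' @param seed Integer seed.
#' @return Data frame with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (BED6).
#' @export
generate_peaks <- function(annotation, bound_gene_ids, window = 1000,
                           jitter_sd = 0, peak_width = 200, seed = 1L) {
  if (window <= 0) stop("`window` must be positive", call. = FALSE)
  missing <- setdiff(bound_gene_ids, annotation$gene_id)
  if (length(missing)) {
    stop(sprintf("gene id(s) absent from annotation: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (length(bound_gene_ids) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = numeric(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  ann <- annotation[match(bound_gene_ids, annotation$gene_id), ]
  with_seed(seed, {
    max_shift <- max(0, window - ceiling(peak_width / 2) - 1)
    jitter <- if (jitter_sd > 0) {
      pmin(pmax(round(rnorm(nrow(ann), 0, jitter_sd)), -max_shift), max_shift)
    } else 0
    mid <- ann$tss + jitter
    start <- pmax(0L, as.integer(mid - floor(peak_width / 2)))
    data.frame(chrom = ann$chrom, start = start,
               end = start + as.integer(peak_width),
               name = paste0("peak_", ann$gene_id),
               score = round(runif(nrow(ann), 100, 1000)),
               strand = ".", stringsAsFactors = FALSE)
  })
}
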