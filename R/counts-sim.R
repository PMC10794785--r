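#' Simulate a raw count matrix from karyotype metadata and ground truth
#'
#' Draws negative binomial counts with per-gene mean
#' `s_j * q_g * 2^(beta_x * nX_j + beta_y * nY_j + beta_21 * (n21_j - 2) +
#' batch_offset)`, where `q_g` is the gene baseline (rescaled so baselines sum
#' to `library_size_mean`) and `s_j` is a log-normal per-sample library size
#' factor centred on 1. Dispersion 0 yields Poisson counts.
#'
#' @param meta Sample metadata from [generate_design()].
#' @param truth Ground truth from [generate_truth()].
#' @param library_size_mean Expected total count per sample.
#' @param library_size_sd SD (log scale) of the per-sample size factor; 0
#'   gives identical library sizes.
#' @param seed Integer seed.
#' @return Integer-valued gene x sample matrix with dimnames.
#' @examples
#' meta <- generate_design(karyotype_design(c("45,X", "47,XXX"), c(3, 3)), 1)
#' truth <- generate_truth(50, 0.2, 0.1, 0.1, seed = 1)
#' counts <- generate_counts(meta, truth, library_size_mean = 1e5, seed = 2)
#' @export
generate_counts <- function(meta, truth, library_size_mean = 2e6,
                            library_size_sd = 0.3, seed = 1L) {
  if (!inherits(truth, "xy_truth")) {
    stop("`truth` must come from generate_truth()", call. = FALSE)
  }
  if (library_size_mean <= 0) {
    stop("`library_size_mean` must be positive", call. = FALSE)
  }
  g <- truth$genes
  n_genes <- nrow(g)
  n_samp <- nrow(meta)
  batches <- colnames(truth$batch_effects)
  if (!all(meta$batch %in% batches)) {
    stop("metadata batches not present in truth batch effects", call. = FALSE)
  }
  q <- g$baseline / sum(g$baseline) * library_size_mean
  with_seed(seed, {
    s <- exp(rnorm(n_samp, 0, library_size_sd))
    log2fc <- outer(g$beta_x, meta$x_count) +
      outer(g$beta_y, meta$y_count) +
      outer(g$beta_21, meta$chr21_count - 2) +
      truth$batch_effects[, match(meta$batch, batches), drop = FALSE]
    mu <- (q * 2^log2fc) * rep(s, each = n_genes)
    size <- rep(1 / pmax(g$dispersion, 1e-12), times = n_samp)
    counts <- matrix(rnbinom(n_genes * n_samp, mu = as.vector(mu),
                             size = size),
                     nrow = n_genes,
                     dimnames = list(g$gene_id, meta$sample_id))
    counts
  })
}
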