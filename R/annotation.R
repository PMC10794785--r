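#' Generate a synthetic gene annotation table
#'
#' Assigns genes to chromosomes, spaced transcription start sites, strands,
#' effective lengths and a coarse class. Autosomal genes are distributed
#' round-robin over chr1-chr22; optional fractions are placed on chrX (class
#' `"NPX"`) and chrY (class `"NPY"`). Coordinates are 0-based; gene spans are
#' half-open `[start, end)`, with the TSS at `start` for `+` strand genes and
#' at `end` for `-` strand genes.
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param frac_x,frac_y Fractions of genes assigned to chrX / chrY.
#' @param spacing Distance in bases between successive TSSs on a chromosome.
#' @param length_meanlog,length_sdlog Log-normal parameters of effective
#'   gene length.
#' @param seed Integer seed (strand and length draws).
#' @return Data frame with columns `gene_id`, `chrom`, `tss`, `strand`,
#'   `start`, `end`, `length`, `class`.
#' @export
generate_annotation <- function(gene_ids, frac_x = 0, frac_y = 0,
                                spacing = 1e5, length_meanlog = log(1500),
                                length_sdlog = 0.5, seed = 1L) {
  n <- length(gene_ids)
  n_x <- round(frac_x * n)
  n_y <- round(frac_y * n)
  if (n_x + n_y > n) stop("frac_x + frac_y must be <= 1", call. = FALSE)
  with_seed(seed, {
    chrom <- character(n)
    cls <- rep("autosomal", n)
    sex_idx <- if (n_x + n_y > 0) sample.int(n, n_x + n_y) else integer(0)
    if (n_x > 0) {
      chrom[sex_idx[seq_len(n_x)]] <- "chrX"
      cls[sex_idx[seq_len(n_x)]] <- "NPX"
    }
    if (n_y > 0) {
      chrom[sex_idx[n_x + seq_len(n_y)]] <- "chrY"
      cls[sex_idx[n_x + seq_len(n_y)]] <- "NPY"
    }
    auto <- which(chrom == "")
    chrom[auto] <- paste0("chr", rep_len(1:22, length(auto)))
    # per-chromosome TSS ladder, 0-based
    tss <- integer(n)
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      tss[i] <- as.integer(spacing * seq_along(i))
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    len <- pmax(200L, as.integer(rlnorm(n, length_meanlog, length_sdlog)))
    start <- ifelse(strand == "+", tss, pmax(0L, tss - len))
    end <- ifelse(strand == "+", tss + len, tss)
    data.frame(gene_id = gene_ids, chrom = chrom, tss = tss, strand = strand,
               start = as.integer(start), end = as.integer(end),
               length = len, class = cls, stringsAsFactors = FALSE)
  })
}
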