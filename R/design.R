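#' Karyotype study designs
#'
#' A karyotype design lists, for each karyotype in a study, the number of
#' samples carrying it, together with the implied X, Y and chromosome 21 copy
#' numbers. Karyotype labels follow ISCN-style shorthand: `"45,X"`,
#' `"47,XXY"`, `"49,XYYYY"`, with an optional trisomy-21 suffix as in
#' `"47,XX+21"`. Every somatic cell carries at least one (active) X
#' chromosome, so designs with zero X copies are rejected.
#'
#' @param karyotypes Character vector of karyotype labels.
#' @param n Integer vector, samples per karyotype (recycled if length 1).
#' @param batches Character vector of library preparation batch labels.
#' @param cell_type Single label for the cell type the design describes.
#' @return An object of class `karyotype_design`: a data frame with columns
#'   `karyotype`, `x_count`, `y_count`, `chr21_count`, `n`, and attributes
#'   `batches` and `cell_type`.
#' @examples
#' karyotype_design(c("45,X", "46,XX", "47,XYY"), c(3, 4, 2))
#' @export
karyotype_design <- function(karyotypes, n,
                             batches = c("batch1", "batch2", "batch3"),
                             cell_type = "LCL") {
  stopifnot(is.character(karyotypes))
  n <- as.integer(rep_len(n, length(karyotypes)))
  if (any(is.na(n)) || any(n < 0)) {
    stop("sample counts `n` must be non-negative integers", call. = FALSE)
  }
  parsed <- lapply(karyotypes, parse_karyotype)
  x <- vapply(parsed, `[[`, integer(1), "x")
  y <- vapply(parsed, `[[`, integer(1), "y")
  c21 <- vapply(parsed, `[[`, integer(1), "chr21")
  bad <- which(x < 1L)
  if (length(bad)) {
    stop(sprintf("karyotype entry '%s' has zero X chromosomes; %s",
                 karyotypes[bad[1]],
                 "all somatic cells carry at least one active X"),
         call. = FALSE)
  }
  out <- data.frame(karyotype = karyotypes, x_count = x, y_count = y,
                    chr21_count = c21, n = n, stringsAsFactors = FALSE)
  attr(out, "batches") <- batches
  attr(out, "cell_type") <- cell_type
  class(out) <- c("karyotype_design", class(out))
  out
}

parse_karyotype <- function(label) {
  sex <- sub("^[0-9]+,", "", label)
  chr21 <- 2L + as.integer(grepl("\\+21", sex))
  sex <- sub("\\+21", "", sex)
  chars <- strsplit(sex, "")[[1]]
  if (!all(chars %in% c("X", "Y"))) {
    stop(sprintf("cannot parse karyotype label '%s'", label), call. = FALSE)
  }
  list(x = sum(chars == "X"), y = sum(chars == "Y"), chr21 = chr21)
}

#' Lymphoblastoid cell line karyotype series
#'
#' The 106-sample LCL design spanning 45,X to 49,XXXXY and 49,XYYYY.
#'
#' @param batches,cell_type Passed to [karyotype_design()].
#' @return A `karyotype_design` totalling 106 samples.
#' @export
lcl_design <- function(batches = c("batch1", "batch2", "batch3"),
                       cell_type = "LCL") {
  karyotype_design(
    c("45,X", "46,XX", "46,XY", "47,XXX", "47,XXY", "47,XYY", "48,XXXX",
      "48,XXXY", "48,XXYY", "49,XXXXY", "49,XYYYY"),
    c(17L, 22L, 17L, 7L, 11L, 10L, 1L, 4L, 3L, 12L, 2L),
    batches = batches, cell_type = cell_type
  )
}

#' Fibroblast karyotype series
#'
#' The 99-sample primary dermal fibroblast design.
#'
#' @inheritParams lcl_design
#' @return A `karyotype_design` totalling 99 samples.
#' @export
fibroblast_design <- function(batches = c("batch1", "batch2", "batch3"),
                              cell_type = "fibroblast") {
  karyotype_design(
    c("45,X", "46,XX", "46,XY", "47,XXX", "47,XXY", "47,XYY", "48,XXXY",
      "49,XXXXY", "49,XYYYY"),
    c(23L, 20L, 14L, 4L, 30L, 5L, 1L, 1L, 1L),
    batches = batches, cell_type = cell_type
  )
}

#' Expand a karyotype design into per-sample metadata
#'
#' Produces one row per sample with karyotype covariates. Batches are assigned
#' round-robin across samples and then shuffled, so batch is balanced across
#' karyotypes but not confounded with them; the shuffle (and therefore the
#' whole table) is deterministic for a fixed seed.
#'
#' @param design A [karyotype_design()].
#' @param seed Integer seed for the batch shuffle.
#' @return Data frame with columns `sample_id`, `karyotype`, `x_count`,
#'   `y_count`, `xi_count` (= `x_count` - 1), `chr21_count`, `batch`,
#'   `cell_type`.
#' @examples
#' meta <- generate_design(lcl_design(), seed = 1)
#' nrow(meta)  # 106
#' @export
generate_design <- function(design, seed = 1L) {
  if (!inherits(design, "karyotype_design")) {
    stop("`design` must be created with karyotype_design()", call. = FALSE)
  }
  total <- sum(design$n)
  batches <- attr(design, "batches")
  cell_type <- attr(design, "cell_type")
  if (total == 0L) {
    return(data.frame(sample_id = character(0), karyotype = character(0),
                      x_count = integer(0), y_count = integer(0),
                      xi_count = integer(0), chr21_count = integer(0),
                      batch = character(0), cell_type = character(0),
                      stringsAsFactors = FALSE))
  }
  idx <- rep(seq_len(nrow(design)), times = design$n)
  meta <- data.frame(
    sample_id = sprintf("s%03d", seq_len(total)),
    karyotype = design$karyotype[idx],
    x_count = design$x_count[idx],
    y_count = design$y_count[idx],
    xi_count = design$x_count[idx] - 1L,
    chr21_count = design$chr21_count[idx],
    stringsAsFactors = FALSE
  )
  meta$batch <- with_seed(seed, {
    rep_len(batches, total)[sample.int(total)]
  })
  meta$cell_type <- cell_type
  meta
}
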