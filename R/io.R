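#' Read and write pipeline file formats
#'
#' Plain-text readers and writers for every format the pipeline consumes or
#' produces. All pairs are lossless round-trips on the in-memory data
#' model; BED coordinates are preserved exactly.
#'
#' * counts: TSV with gene ids in the first column (`write_counts_tsv` /
#'   `read_counts_tsv`), or a MatrixMarket triple `<prefix>.mtx`,
#'   `<prefix>.genes.txt`, `<prefix>.samples.txt` (`write_counts_mtx` /
#'   `read_counts_mtx`);
#' * tables: sample metadata, gene annotation, effect fits and other
#'   data frames as TSV (`write_table_tsv` / `read_table_tsv`);
#' * intervals: 6-column BED, 0-based half-open (`write_bed` /
#'   `read_bed`), with malformed lines reported by line number;
#' * categories: GMT-style text, one category per line
#'   (`name<TAB>description<TAB>gene...`; `write_gmt` / `read_gmt`).
#'
#' @param counts,x Object to write.
#' @param path,prefix Destination file (or MTX prefix).
#' @param bed,peaks Peak data frame with `chrom`, `start`, `end` and
#'   optionally `name`, `score`, `strand`.
#' @param categories Named list of character vectors.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname pipeline_io
#' @export
write_counts_mtx <- function(counts, prefix) {
  sm <- Matrix::Matrix(counts, sparse = TRUE)
  Matrix::writeMM(sm, paste0(prefix, ".mtx"))
  writeLines(rownames(counts), paste0(prefix, ".genes.txt"))
  writeLines(colnames(counts), paste0(prefix, ".samples.txt"))
  invisible(prefix)
}

#' @rdname pipeline_io
#' @export
read_counts_mtx <- function(prefix) {
  m <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  rownames(m) <- readLines(paste0(prefix, ".genes.txt"))
  colnames(m) <- readLines(paste0(prefix, ".samples.txt"))
  storage.mode(m) <- "double"
  m
}

#' @rdname pipeline_io
#' @export
write_table_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_table_tsv <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname pipeline_io
#' @export
write_bed <- function(peaks, path) {
  validate_peaks(peaks)
  df <- data.frame(chrom = peaks$chrom, start = peaks$start,
                   end = peaks$end,
                   name = peaks$name %||% ".",
                   score = peaks$score %||% 0,
                   strand = peaks$strand %||% ".")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 3) {
      stop(sprintf("malformed BED line %d: fewer than 3 fields", i),
           call. = FALSE)
    }
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end) || start < 0 || start >= end) {
      stop(sprintf("malformed BED line %d: bad coordinates '%s' '%s'",
                   i, f[2], f[3]), call. = FALSE)
    }
    data.frame(chrom = f[1], start = as.integer(start),
               end = as.integer(end),
               name = if (length(f) >= 4) f[4] else ".",
               score = if (length(f) >= 5) {
                 suppressWarnings(as.numeric(f[5]))
               } else 0,
               strand = if (length(f) >= 6) f[6] else ".",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname pipeline_io
#' @export
write_gmt <- function(categories, path) {
  lines <- vapply(names(categories), function(nm) {
    paste(c(nm, nm, categories[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3) {
      stop("malformed GMT line: need name, description and >= 1 gene",
           call. = FALSE)
    }
    f[-(1:2)]
  })
  names(out) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`,
                       character(1), 1)
  out
}

#' @rdname pipeline_io
#' @export
write_depth_tsv <- function(x, path) write_table_tsv(x, path)

#' @rdname pipeline_io
#' @export
read_depth_tsv <- function(path) read_table_tsv(path)
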