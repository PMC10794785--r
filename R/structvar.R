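#' GC-bias correction of a windowed depth profile
#'
#' Bins single-copy windows into `n_bins` equal-width GC bins and scales
#' depths within each bin by `global single-copy median / bin median`.
#' Repeat-region windows are corrected with the factors fitted on the
#' single-copy region (their own depths never influence the correction);
#' windows with GC outside the fitted range use the nearest bin. Empty or
#' zero-median bins leave depths unchanged.
#'
#' @param profile Depth profile data frame with columns `gc`, `depth`,
#'   `region` (values `"repeat"` / `"single_copy"`).
#' @param n_bins Number of equal-width GC bins.
#' @return The profile with `depth` corrected and the raw depth preserved
#'   in `depth_raw`.
#' @export
gc_correct <- function(profile, n_bins = 10) {
  sc <- profile$region == "single_copy"
  if (!any(sc)) stop("profile has no single-copy windows", call. = FALSE)
  gc_sc <- profile$gc[sc]
  rng <- range(gc_sc)
  breaks <- if (rng[1] == rng[2]) {
    c(rng[1] - 0.5, rng[1] + 0.5)
  } else {
    seq(rng[1], rng[2], length.out = n_bins + 1)
  }
  bin_of <- function(gc) {
    pmin(pmax(findInterval(gc, breaks, rightmost.closed = TRUE), 1),
         length(breaks) - 1)
  }
  global_med <- median(profile$depth[sc])
  factors <- vapply(seq_len(length(breaks) - 1), function(b) {
    d <- profile$depth[sc][bin_of(gc_sc) == b]
    m <- if (length(d)) median(d) else NA_real_
    if (is.na(m) || m == 0 || global_med == 0) 1 else global_med / m
  }, numeric(1))
  out <- profile
  out$depth_raw <- profile$depth
  out$depth <- profile$depth * factors[bin_of(profile$gc)]
  out
}

#' Normalized repeat-array depth
#'
#' Mean depth over repeat windows divided by mean depth over single-copy
#' windows: a sequencing-depth-invariant estimate of repeat copy number
#' relative to single copy (higher coverage implies a longer array).
#'
#' @param profile Depth profile with a `region` column.
#' @return A single positive number.
#' @export
normalized_repeat_depth <- function(profile) {
  rep_mean <- mean(profile$depth[profile$region == "repeat"])
  sc_mean <- mean(profile$depth[profile$region == "single_copy"])
  if (!is.finite(sc_mean) || sc_mean <= 0) {
    stop("single-copy mean depth must be positive", call. = FALSE)
  }
  rep_mean / sc_mean
}

#' Variance-stabilizing log transform
#'
#' `log2(x + 1)` on normalized counts: a monotone, parameter-free
#' stand-in for dispersion-based variance stabilization, adequate for
#' clustering and ordination.
#'
#' @param x Non-negative numeric vector or matrix of normalized counts.
#' @return Transformed values, same shape.
#' @export
vst_log <- function(x) {
  if (any(x < 0)) stop("normalized counts must be non-negative", call. = FALSE)
  log2(x + 1)
}

#' Remove batch structure from an expression matrix
#'
#' Per gene, subtracts batch means and restores the grand mean (linear
#' batch regression with the intercept retained), leaving within-batch
#' contrasts untouched. With fewer than two batches the matrix is returned
#' unchanged with a warning.
#'
#' @param mat Gene x sample numeric matrix (e.g. [vst_log()] output).
#' @param batch Batch label per sample.
#' @return Residualized matrix of the same shape.
#' @export
remove_batch <- function(mat, batch) {
  stopifnot_matrix(mat)
  batch <- factor(batch)
  if (length(batch) != ncol(mat)) {
    stop("one batch label per sample is required", call. = FALSE)
  }
  if (nlevels(batch) < 2) {
    warning("fewer than two batches: nothing to remove", call. = FALSE)
    return(mat)
  }
  grand <- rowMeans(mat)
  out <- mat
  for (b in levels(batch)) {
    cols <- which(batch == b)
    out[, cols] <- mat[, cols] - rowMeans(mat[, cols, drop = FALSE]) + grand
  }
  out
}

#' Principal component analysis of samples over a gene subset
#'
#' Centred PCA with samples as observations and genes as variables.
#' Component signs are fixed so the largest-magnitude loading of each
#' component is positive, making scores deterministic.
#'
#' @param mat Gene x sample matrix (transformed expression).
#' @param genes Gene subset to use (default all rows; must have length
#'   >= `k`).
#' @param k Number of components to retain.
#' @return Object of class `xy_pca`: `scores` (samples x k), `loadings`
#'   (genes x k, orthonormal), `explained` (variance fractions), `center`.
#' @export
pca_project <- function(mat, genes = NULL, k = 2) {
  stopifnot_matrix(mat)
  genes <- genes %||% rownames(mat)
  missing <- setdiff(genes, rownames(mat))
  if (length(missing)) {
    stop(sprintf("gene(s) absent from matrix: %s",
                 paste(head(missing, 5), collapse = ", ")), call. = FALSE)
  }
  if (length(genes) < k) stop("need at least k genes", call. = FALSE)
  z <- t(mat[genes, , drop = FALSE])
  if (nrow(z) < k + 1) stop("need at least k + 1 samples", call. = FALSE)
  if (all(apply(z, 2, var) == 0)) {
    stop("constant matrix: PCA undefined", call. = FALSE)
  }
  pc <- prcomp(z, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$rotation))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  for (m in seq_len(k)) {
    j <- which.max(abs(loadings[, m]))
    if (loadings[j, m] < 0) {
      loadings[, m] <- -loadings[, m]
      scores[, m] <- -scores[, m]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
                 center = pc$center),
            class = "xy_pca")
}

#' Group centroids in component space
#'
#' @param scores Sample x component score matrix.
#' @param groups Group label per sample.
#' @param min_n Minimum group size to report a centroid.
#' @return Matrix of centroids (groups x components).
#' @export
group_centroids <- function(scores, groups, min_n = 1) {
  groups <- as.character(groups)
  tab <- table(groups)
  keep <- names(tab)[tab >= min_n]
  out <- t(vapply(keep, function(g) {
    colMeans(scores[groups == g, , drop = FALSE])
  }, numeric(ncol(scores))))
  rownames(out) <- keep
  out
}

#' Confidence ellipses around group centroids
#'
#' For each group with at least `min_n` samples, builds the `level`
#' confidence ellipse of the centroid from the covariance of the mean
#' (group score covariance divided by n) scaled by the chi-square quantile
#' with 2 degrees of freedom.
#'
#' @param scores Sample x 2 score matrix.
#' @param groups Group label per sample.
#' @param level Confidence level.
#' @param min_n Minimum group size for an ellipse.
#' @return Data frame with one row per qualifying group: `group`, `n`,
#'   `center_x`, `center_y`, `semi_major`, `semi_minor`, `angle` (radians,
#'   major-axis orientation).
#' @export
centroid_ellipses <- function(scores, groups, level = 0.95, min_n = 3) {
  if (ncol(scores) < 2) stop("need 2-D scores", call. = FALSE)
  scores <- scores[, 1:2, drop = FALSE]
  groups <- as.character(groups)
  q <- qchisq(level, df = 2)
  rows <- lapply(unique(groups), function(g) {
    s <- scores[groups == g, , drop = FALSE]
    n <- nrow(s)
    if (n < min_n) return(NULL)
    ctr <- colMeans(s)
    cov_mean <- stats::cov(s) / n
    eig <- eigen(cov_mean, symmetric = TRUE)
    axes <- sqrt(pmax(eig$values, 0) * q)
    data.frame(group = g, n = n, center_x = ctr[1], center_y = ctr[2],
               semi_major = axes[1], semi_minor = axes[2],
               angle = atan2(eig$vectors[2, 1], eig$vectors[1, 1]),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Nearest-centroid placement of structural-variant samples
#'
#' Assigns each sample the label of the nearest reference karyotype
#' centroid (Euclidean distance in the first two components). Exact ties go
#' to the lexicographically first label and are flagged.
#'
#' @param scores Sample x component score matrix (rows named by sample).
#' @param reference_centroids Centroid matrix from [group_centroids()]
#'   (>= 2 rows).
#' @return Data frame: `sample`, `label`, `distance`, `tie`.
#' @export
classify_variant <- function(scores, reference_centroids) {
  if (is.null(dim(reference_centroids)) || nrow(reference_centroids) < 2) {
    stop("need at least 2 reference centroids", call. = FALSE)
  }
  d <- min(2, ncol(scores), ncol(reference_centroids))
  ctr <- reference_centroids[order(rownames(reference_centroids)),
                             seq_len(d), drop = FALSE]
  sc <- scores[, seq_len(d), drop = FALSE]
  rows <- lapply(seq_len(nrow(sc)), function(i) {
    dist <- sqrt(colSums((t(ctr) - sc[i, ])^2))
    j <- which.min(dist)
    data.frame(sample = rownames(sc)[i] %||% as.character(i),
               label = rownames(ctr)[j], distance = dist[j],
               tie = sum(dist == dist[j]) > 1,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}
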