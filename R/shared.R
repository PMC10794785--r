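#' Hypergeometric overlap test between two gene sets
#'
#' Tests whether two subsets of a common universe overlap more than expected
#' by chance, using the upper-tail hypergeometric probability including the
#' observed count, `P(X >= |A intersect B|)`.
#'
#' @param set_a,set_b Character vectors, both subsets of `universe`.
#' @param universe Character vector of all eligible elements.
#' @param n_tests Bonferroni denominator for the adjusted p value.
#' @return List of class `overlap_result`: `n_a`, `n_b`, `n_overlap`,
#'   `n_universe`, `p_value`, `p_bonferroni`, and `venn` (a-only, b-only,
#'   both).
#' @examples
#' overlap_test(letters[1:5], letters[4:5], letters[1:10])
#' @export
overlap_test <- function(set_a, set_b, universe, n_tests = 1) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  out_a <- setdiff(set_a, universe)
  out_b <- setdiff(set_b, universe)
  if (length(out_a) || length(out_b)) {
    stop(sprintf("element(s) outside the universe: %s",
                 paste(head(c(out_a, out_b), 5), collapse = ", ")),
         call. = FALSE)
  }
  n <- length(universe)
  k <- length(intersect(set_a, set_b))
  p <- phyper(k - 1, length(set_a), n - length(set_a), length(set_b),
              lower.tail = FALSE)
  structure(list(
    n_a = length(set_a), n_b = length(set_b), n_overlap = k,
    n_universe = n, p_value = p, p_bonferroni = min(1, p * n_tests),
    venn = c(a_only = length(set_a) - k, b_only = length(set_b) - k,
             both = k)),
    class = "overlap_result")
}

#' @method print overlap_result
#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: %d of |A|=%d, |B|=%d in universe %d; p=%.3g (Bonferroni %.3g)\n",
              x$n_overlap, x$n_a, x$n_b, x$n_universe, x$p_value,
              x$p_bonferroni))
  invisible(x)
}

extract_estimates <- function(fit, genes, coef = NULL) {
  if (is.data.frame(fit)) {
    if (!is.null(coef)) fit <- fit[fit$coef == coef, ]
    if (length(unique(fit$coef)) > 1) {
      stop("fit contains several coefficients; supply `coef`", call. = FALSE)
    }
    est <- setNames(fit$log2fc_per_copy, fit$gene)
  } else {
    est <- fit
  }
  missing <- setdiff(genes, names(est))
  if (length(missing)) {
    stop(sprintf("gene(s) absent from fit: %s",
                 paste(head(missing, 5), collapse = ", ")), call. = FALSE)
  }
  est[genes]
}

#' Correlate two effect catalogs over a gene set
#'
#' Pearson correlation of per-gene effect estimates (log2 fold change per
#' copy) from two fits, with Bonferroni adjustment over a stated number of
#' tests. The denominator `n_tests` is an explicit argument: it depends on
#' how many comparisons a figure or analysis draws and is never inferred.
#'
#' @param fit_a,fit_b `effect_fit` tables (single coefficient, or supply
#'   `coef_a` / `coef_b`) or named numeric vectors of estimates.
#' @param genes Genes to correlate (>= 3, present in both fits).
#' @param n_tests Bonferroni denominator.
#' @param coef_a,coef_b Coefficient to extract when a fit holds several.
#' @return List with `r`, `p_value`, `p_bonferroni`, `n`.
#' @export
correlate_effects <- function(fit_a, fit_b, genes, n_tests = 1,
                              coef_a = NULL, coef_b = NULL) {
  if (length(genes) < 3) stop("need at least 3 genes", call. = FALSE)
  a <- extract_estimates(fit_a, genes, coef_a)
  b <- extract_estimates(fit_b, genes, coef_b)
  if (sd(a) == 0 || sd(b) == 0) {
    stop("constant estimate vector: correlation undefined", call. = FALSE)
  }
  ct <- cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value,
       p_bonferroni = min(1, ct$p.value * n_tests), n = length(genes))
}

#' Weighted (generalized) Deming regression
#'
#' Errors-in-variables straight-line fit for two variables both measured
#' with error. The slope minimizes the error-scaled orthogonal objective
#' `sum_i (y_i - a - b x_i)^2 / (ystd_i^2 + b^2 xstd_i^2)` with the
#' intercept profiled out (iteratively reweighted, Linnet-style); with
#' constant equal errors this reduces to classical Deming regression with
#' variance ratio 1. The slope standard error is a leave-one-out jackknife
#' and the 95% confidence interval is normal-theory (`slope +/- 1.96 SE`).
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @param xstd,ystd Per-point error SDs (> 0); both default to 1 (unweighted
#'   Deming with variance ratio 1).
#' @param conf Confidence level for the slope interval.
#' @return Object of class `deming_fit`: `slope`, `intercept`, `se_slope`,
#'   `ci` (length 2), `n`, `xstd`, `ystd`.
#' @examples
#' x <- 1:10
#' weighted_deming(x, 2 * x)$slope  # 2
#' @export
weighted_deming <- function(x, y, xstd = NULL, ystd = NULL, conf = 0.95) {
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length", call. = FALSE)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  if (var(x) == 0) stop("`x` has zero variance", call. = FALSE)
  xstd <- xstd %||% rep(1, n)
  ystd <- ystd %||% rep(1, n)
  xstd <- rep_len(xstd, n); ystd <- rep_len(ystd, n)
  if (any(xstd <= 0) || any(ystd <= 0)) {
    stop("error SDs must be positive", call. = FALSE)
  }
  slope <- deming_slope(x, y, xstd, ystd)
  w <- 1 / (ystd^2 + slope^2 * xstd^2)
  intercept <- sum(w * (y - slope * x)) / sum(w)
  jack <- vapply(seq_len(n), function(i) {
    deming_slope(x[-i], y[-i], xstd[-i], ystd[-i])
  }, numeric(1))
  se <- sqrt((n - 1) / n * sum((jack - mean(jack))^2))
  zq <- qnorm((1 + conf) / 2)
  structure(list(slope = slope, intercept = intercept, se_slope = se,
                 ci = c(slope - zq * se, slope + zq * se), n = n,
                 xstd = xstd, ystd = ystd),
            class = "deming_fit")
}

deming_slope <- function(x, y, xstd, ystd) {
  obj <- function(b) {
    w <- 1 / (ystd^2 + b^2 * xstd^2)
    a <- sum(w * (y - b * x)) / sum(w)
    sum(w * (y - a - b * x)^2)
  }
  # bracket from the two extreme regressions (y on x, and inverse)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  cand <- c(sxy / sxx, if (sxy != 0) syy / sxy else 0, 0)
  span <- max(abs(cand)) + 1
  lo <- min(cand) - 2 * span
  hi <- max(cand) + 2 * span
  b <- optimize(obj, c(lo, hi), tol = 1e-10)$minimum
  # polish on a narrow interval for near machine-precision slopes
  h <- 1e-4 * (abs(b) + 1)
  optimize(obj, c(b - h, b + h), tol = 1e-14)$minimum
}

#' @method print deming_fit
#' @export
print.deming_fit <- function(x, ...) {
  cat(sprintf("Deming fit (n=%d): slope %.4f (SE %.4f, CI %.4f..%.4f), intercept %.4f\n",
              x$n, x$slope, x$se_slope, x$ci[1], x$ci[2], x$intercept))
  invisible(x)
}

#' Variance in one effect catalog explained by another
#'
#' Coefficient of determination between two per-gene effect vectors,
#' computed as the squared Pearson correlation, with the sign of the
#' association reported separately (a perturbation that opposes a dosage
#' response yields R-squared near 1 with negative sign).
#'
#' @inheritParams correlate_effects
#' @return List with `r_squared`, `sign` (-1, 0 or 1), `p_value`,
#'   `p_bonferroni`, `n`.
#' @export
variance_explained <- function(fit_a, fit_b, genes, n_tests = 1,
                               coef_a = NULL, coef_b = NULL) {
  ce <- correlate_effects(fit_a, fit_b, genes, n_tests, coef_a, coef_b)
  list(r_squared = ce$r^2, sign = sign(ce$r), p_value = ce$p_value,
       p_bonferroni = ce$p_bonferroni, n = ce$n)
}

#' Gene category enrichment by hypergeometric test
#'
#' Upper-tail hypergeometric enrichment of a gene set in each category,
#' against a stated background universe, with Benjamini-Hochberg control
#' across categories.
#'
#' @param gene_set Genes of interest (subset of `universe`).
#' @param categories Named list of gene-id vectors (e.g. read with
#'   [read_gmt()]).
#' @param universe Background gene set.
#' @param fdr FDR threshold for the `significant` flag.
#' @return Data frame with one row per non-empty category: `category`,
#'   `n_category`, `n_overlap`, `p`, `q`, `significant`. Empty categories
#'   (after restriction to the universe) are skipped with a warning giving
#'   their count.
#' @export
category_enrichment <- function(gene_set, categories, universe, fdr = 0.05) {
  gene_set <- unique(gene_set)
  bad <- setdiff(gene_set, universe)
  if (length(bad)) {
    stop(sprintf("gene(s) outside the universe: %s",
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  restricted <- lapply(categories, intersect, universe)
  empty <- vapply(restricted, length, integer(1)) == 0
  if (any(empty)) {
    warning(sprintf("%d empty categor%s skipped", sum(empty),
                    if (sum(empty) == 1) "y" else "ies"), call. = FALSE)
    restricted <- restricted[!empty]
  }
  n <- length(universe)
  rows <- lapply(names(restricted), function(nm) {
    cat_genes <- restricted[[nm]]
    k <- length(intersect(gene_set, cat_genes))
    p <- phyper(k - 1, length(gene_set), n - length(gene_set),
                length(cat_genes), lower.tail = FALSE)
    data.frame(category = nm, n_category = length(cat_genes),
               n_overlap = k, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(category = character(0), n_category = integer(0),
                      n_overlap = integer(0), p = numeric(0), q = numeric(0),
                      significant = logical(0)))
  }
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q < fdr
  out
}
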