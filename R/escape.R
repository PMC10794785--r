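#' Allelic-ratio conversions
#'
#' `ar_from_xa_fraction` converts an active-X read fraction (Xa reads /
#' total reads) to an allelic ratio `AR = 1/f - 1` (inactive over active
#' allele); `xa_fraction_from_ar` is its inverse, `f = 1/(1 + AR)`. At
#' `f = 0.95` the conversion gives 0.0526 (4 dp), the per-sample Xi
#' expression threshold used by the single-cell fibroblast dataset.
#' `baseline_ar` gives the allelic ratio expected from incomplete
#' X-inactivation skewing alone, `(1 - skew)/skew`, for a skewing
#' coefficient in `[0.5, 1]`.
#'
#' @param f Xa read fraction in (0, 1].
#' @param ar Allelic ratio >= 0.
#' @param skew Skewing coefficient in [0.5, 1].
#' @return Numeric vector.
#' @examples
#' round(ar_from_xa_fraction(0.95), 4)  # 0.0526
#' baseline_ar(0.9)                     # 1/9
#' @export
ar_from_xa_fraction <- function(f) {
  if (any(f <= 0 | f > 1)) {
    stop("Xa fraction must lie in (0, 1]", call. = FALSE)
  }
  1 / f - 1
}

#' @rdname ar_from_xa_fraction
#' @export
xa_fraction_from_ar <- function(ar) {
  if (any(ar < 0)) stop("allelic ratio must be >= 0", call. = FALSE)
  1 / (1 + ar)
}

#' @rdname ar_from_xa_fraction
#' @export
baseline_ar <- function(skew) {
  if (any(skew < 0.5 | skew > 1)) {
    stop("skewing coefficient must lie in [0.5, 1]", call. = FALSE)
  }
  (1 - skew) / skew
}

# One-sided one-sample t p-value for mean > 0, with degenerate-variance
# conventions: constant positive values -> p 0 (certainty), constant
# non-positive -> p 1; both flagged.
one_sided_p <- function(values) {
  n <- length(values)
  m <- mean(values)
  s <- sd(values)
  if (is.na(s) || s == 0) {
    list(p = if (m > 0) 0 else 1,
         flag = if (m > 0) "degenerate_positive" else "zero_variance")
  } else {
    list(p = pt(m * sqrt(n) / s, df = n - 1, lower.tail = FALSE), flag = NA)
  }
}

dataset_call <- function(gene, dataset, call, mean_ar, n_informative,
                         flag = NA_character_) {
  data.frame(gene = gene, dataset = dataset, call = call,
             mean_ar = mean_ar, n_informative = n_informative, flag = flag,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-dataset Xi-escape callers
#'
#' Each caller re-implements one published study's rule for deciding,
#' per gene, whether there is evidence of expression from the inactive X.
#' Genes not meeting a dataset's inclusion criteria are `no_data`;
#' otherwise the call is `escape` or `subject`.
#'
#' * `call_cotton`: per-gene mean AR, SD and n from SNP-chip allelic data;
#'   genes informative in at least `min_n` samples are tested with a
#'   one-sided one-sample t-test of mean AR > 0, BH-adjusted; escape at
#'   adjusted p < `alpha`. A zero SD with positive mean is degenerate
#'   certainty (p = 0, flagged).
#' * `call_tukiainen`: single-cell calls per individual plus a bulk call; a
#'   gene is included with data from >= 2 single-cell individuals, or 1
#'   individual plus bulk; escape if any included sub-dataset is
#'   significant (adjusted p < `alpha`).
#' * `call_garieri`: per-sample Xa fractions (or ARs) from single-cell
#'   fibroblasts; included with >= `min_samples` samples; escape if any
#'   sample's AR exceeds `threshold` (0.0526, i.e. Xa fraction < 0.95).
#' * `call_sauteraud`: per-sample raw ARs with skewing coefficients;
#'   included with >= `min_n` samples; paired one-sided t-test of raw AR
#'   minus the skewing baseline `(1-skew)/skew` > 0, BH-adjusted, escape at
#'   adjusted p < `alpha` (default 0.01).
#' * `call_sanroman`: per-sample skew-adjusted ARs; as `call_cotton` on raw
#'   samples, needing >= `min_n` (2) samples.
#'
#' @param data Data frame in the dataset's dialect (see Details of each).
#' @param single_cell,bulk For `call_tukiainen`: data frames
#'   `gene, individual, ar, padj` and `gene, ar, padj`.
#' @param alpha Significance threshold on the BH-adjusted p.
#' @param min_n,min_samples Minimum informative samples for inclusion.
#' @param threshold Per-sample AR threshold (`call_garieri`).
#' @return Data frame (one row per gene): `gene`, `dataset`, `call`,
#'   `mean_ar`, `n_informative`, `flag`.
#' @name dataset_callers
NULL

#' @rdname dataset_callers
#' @export
call_cotton <- function(data, alpha = 0.05, min_n = 5) {
  stopifnot(all(c("gene", "mean_ar", "sd_ar", "n") %in% names(data)))
  included <- data$n >= min_n
  out <- dataset_call(data$gene, "cotton",
                      ifelse(included, "subject", "no_data"),
                      ifelse(included, data$mean_ar, NA_real_),
                      ifelse(included, data$n, 0L))
  if (any(included)) {
    d <- data[included, ]
    degen <- d$sd_ar == 0
    p <- numeric(nrow(d))
    p[degen] <- ifelse(d$mean_ar[degen] > 0, 0, 1)
    t_ok <- !degen
    p[t_ok] <- pt(d$mean_ar[t_ok] * sqrt(d$n[t_ok]) / d$sd_ar[t_ok],
                  df = d$n[t_ok] - 1, lower.tail = FALSE)
    padj <- p.adjust(p, method = "BH")
    out$call[included] <- ifelse(padj < alpha, "escape", "subject")
    out$flag[included][degen & d$mean_ar > 0] <- "degenerate_positive"
  }
  out
}

#' @rdname dataset_callers
#' @export
call_tukiainen <- function(single_cell, bulk, alpha = 0.05) {
  genes <- unique(c(single_cell$gene, bulk$gene))
  rows <- lapply(genes, function(g) {
    sc <- single_cell[single_cell$gene == g, , drop = FALSE]
    bk <- bulk[bulk$gene == g, , drop = FALSE]
    n_ind <- length(unique(sc$individual))
    has_bulk <- nrow(bk) > 0
    included <- n_ind >= 2 || (n_ind == 1 && has_bulk)
    if (!included) {
      return(dataset_call(g, "tukiainen", "no_data", NA_real_, 0L))
    }
    evidence <- any(sc$padj < alpha) || (has_bulk && any(bk$padj < alpha))
    ars <- c(sc$ar, bk$ar)
    dataset_call(g, "tukiainen", if (evidence) "escape" else "subject",
                 mean(ars), n_ind + as.integer(has_bulk))
  })
  do.call(rbind, rows)
}

#' @rdname dataset_callers
#' @export
call_garieri <- function(data, min_samples = 2, threshold = 0.0526) {
  if (!"ar" %in% names(data)) {
    if (!"xa_fraction" %in% names(data)) {
      stop("need an `ar` or `xa_fraction` column", call. = FALSE)
    }
    data$ar <- ar_from_xa_fraction(data$xa_fraction)
  }
  if (any(data$ar < 0)) stop("allelic ratios must be >= 0", call. = FALSE)
  rows <- lapply(split(data, data$gene), function(d) {
    if (nrow(d) < min_samples) {
      return(dataset_call(d$gene[1], "garieri", "no_data", NA_real_, 0L))
    }
    dataset_call(d$gene[1], "garieri",
                 if (any(d$ar > threshold)) "escape" else "subject",
                 mean(d$ar), nrow(d))
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' @rdname dataset_callers
#' @export
call_sauteraud <- function(data, alpha = 0.01, min_n = 10) {
  stopifnot(all(c("gene", "raw_ar", "skew") %in% names(data)))
  per_gene <- split(data, data$gene)
  diffs <- lapply(per_gene, function(d) d$raw_ar - baseline_ar(d$skew))
  included <- vapply(per_gene, nrow, integer(1)) >= min_n
  genes <- names(per_gene)
  out <- dataset_call(genes, "sauteraud",
                      ifelse(included, "subject", "no_data"),
                      NA_real_, 0L)
  out$mean_ar[included] <- vapply(diffs[included], function(d) {
    max(mean(d), 0)
  }, numeric(1))
  out$n_informative[included] <-
    vapply(per_gene[included], nrow, integer(1))
  if (any(included)) {
    tests <- lapply(diffs[included], one_sided_p)
    p <- vapply(tests, `[[`, numeric(1), "p")
    padj <- p.adjust(p, method = "BH")
    out$call[included] <- ifelse(padj < alpha, "escape", "subject")
    out$flag[included] <- vapply(tests, function(t) {
      if (is.na(t$flag)) NA_character_ else t$flag
    }, character(1))
  }
  out
}

#' @rdname dataset_callers
#' @export
call_sanroman <- function(data, alpha = 0.05, min_n = 2) {
  stopifnot(all(c("gene", "ar") %in% names(data)))
  per_gene <- split(data, data$gene)
  included <- vapply(per_gene, nrow, integer(1)) >= min_n
  genes <- names(per_gene)
  out <- dataset_call(genes, "sanroman",
                      ifelse(included, "subject", "no_data"),
                      NA_real_, 0L)
  out$mean_ar[included] <- vapply(per_gene[included], function(d) {
    mean(d$ar)
  }, numeric(1))
  out$n_informative[included] <-
    vapply(per_gene[included], nrow, integer(1))
  if (any(included)) {
    tests <- lapply(per_gene[included], function(d) one_sided_p(d$ar))
    p <- vapply(tests, `[[`, numeric(1), "p")
    padj <- p.adjust(p, method = "BH")
    out$call[included] <- ifelse(padj < alpha, "escape", "subject")
    out$flag[included] <- vapply(tests, function(t) {
      if (is.na(t$flag)) NA_character_ else t$flag
    }, character(1))
  }
  out
}

#' Synthesize per-dataset escape calls into a final verdict
#'
#' Combines up to five dataset calls per gene. Over informative datasets
#' (call not `no_data`), with `nE` escape and `nS` subject calls out of
#' `nI`, and the average AR taken as the unweighted mean of per-dataset mean
#' ARs, the final call is:
#'
#' * `escape` if `nE > nI/2`, or if `0 < nE <= nI/2` and (`nE >= 2` or
#'   average AR >= 0.1);
#' * otherwise `subject` if `nE == 0` (unanimity) or (`nS > nI/2` and
#'   average AR < 0.1);
#' * genes with no informative dataset fall back to the Xi-hybrid rule:
#'   `escape` if the hybrid expression fraction is >= 0.22, `subject` if it
#'   is present and below, `no_call` if missing;
#' * anything else is `no_call` (e.g. an exact 1-of-2 escape split with
#'   average AR < 0.1).
#'
#' Escape clauses take precedence over subject clauses; every gene receives
#' exactly one final call.
#'
#' @param calls Data frame of dataset calls (rows from the per-dataset
#'   callers, concatenated): columns `gene`, `dataset`, `call`, `mean_ar`.
#' @param hybrid_fraction Optional data frame `gene`, `fraction` (fraction
#'   of Xi-hybrid cell lines expressing the gene) or named numeric vector.
#' @return Data frame with one row per gene: per-dataset call columns
#'   (`call_<dataset>`), `n_escape`, `n_subject`, `n_informative`,
#'   `avg_ar`, `hybrid_fraction`, `final`.
#' @export
synthesize_calls <- function(calls, hybrid_fraction = NULL) {
  stopifnot(all(c("gene", "dataset", "call") %in% names(calls)))
  if (!"mean_ar" %in% names(calls)) calls$mean_ar <- NA_real_
  hyb <- if (is.null(hybrid_fraction)) {
    numeric(0)
  } else if (is.data.frame(hybrid_fraction)) {
    setNames(hybrid_fraction$fraction, hybrid_fraction$gene)
  } else {
    hybrid_fraction
  }
  genes <- sort(unique(c(calls$gene, names(hyb))))
  datasets <- unique(calls$dataset)
  per_gene <- split(calls, factor(calls$gene, levels = genes))
  rows <- lapply(genes, function(g) {
    d <- per_gene[[g]]
    call_by_ds <- setNames(rep("no_data", length(datasets)), datasets)
    if (!is.null(d) && nrow(d)) call_by_ds[d$dataset] <- d$call
    inf <- !is.null(d) && nrow(d) > 0
    informative <- if (inf) d[d$call != "no_data", , drop = FALSE] else NULL
    n_inf <- if (is.null(informative)) 0L else nrow(informative)
    n_e <- if (n_inf) sum(informative$call == "escape") else 0L
    n_s <- n_inf - n_e
    avg_ar <- if (n_inf) mean(informative$mean_ar, na.rm = TRUE) else NA_real_
    h <- if (g %in% names(hyb)) hyb[[g]] else NA_real_
    final <- if (n_inf == 0) {
      if (is.na(h)) "no_call" else if (h >= 0.22) "escape" else "subject"
    } else if (n_e > n_inf / 2) {
      "escape"
    } else if (n_e > 0 && (n_e >= 2 || (!is.na(avg_ar) && avg_ar >= 0.1))) {
      "escape"
    } else if (n_e == 0) {
      "subject"
    } else if (n_s > n_inf / 2 && !is.na(avg_ar) && avg_ar < 0.1) {
      "subject"
    } else {
      "no_call"
    }
    cbind(data.frame(gene = g, stringsAsFactors = FALSE),
          as.data.frame(as.list(setNames(call_by_ds,
                                         paste0("call_", datasets))),
                        stringsAsFactors = FALSE),
          data.frame(n_escape = n_e, n_subject = n_s, n_informative = n_inf,
                     avg_ar = avg_ar, hybrid_fraction = h, final = final,
                     stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

#' Run the full five-dataset escape meta-analysis
#'
#' Applies each per-dataset caller to its evidence table and synthesizes the
#' calls, mirroring the end-to-end classification of X-linked genes as
#' escaping X inactivation, subject to it, or not callable.
#'
#' @param datasets A list shaped like the output of
#'   [generate_allelic_datasets()]: elements `cotton`, `tukiainen`
#'   (`single_cell` + `bulk`), `garieri`, `sauteraud`, `sanroman`, and
#'   optionally `hybrid`.
#' @param alphas Named list overriding per-dataset significance thresholds.
#' @return The [synthesize_calls()] table.
#' @export
escape_meta <- function(datasets, alphas = list()) {
  a <- function(nm, default) alphas[[nm]] %||% default
  calls <- rbind(
    call_cotton(datasets$cotton, alpha = a("cotton", 0.05)),
    call_tukiainen(datasets$tukiainen$single_cell, datasets$tukiainen$bulk,
                   alpha = a("tukiainen", 0.05)),
    call_garieri(datasets$garieri),
    call_sauteraud(datasets$sauteraud, alpha = a("sauteraud", 0.01)),
    call_sanroman(datasets$sanroman, alpha = a("sanroman", 0.05))
  )
  synthesize_calls(calls, datasets$hybrid)
}
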