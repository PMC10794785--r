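#' Generate per-gene ground truth for a dosage simulation
#'
#' Draws, for each gene, a baseline expression level, log2-per-copy responses
#' to Chr X, Chr Y and Chr 21 dosage, per-batch offsets, a negative binomial
#' dispersion, and an X-inactivation status (escape vs. subject) with an Xi
#' expression fraction. Responsive genes draw their effect from
#' `Normal(0, effect_sd)`; with the default `effect_sd = 0.2` most absolute
#' fold changes per copy are below 1.5x, matching the modest effect sizes the
#' dosage model is meant to detect. Shared genes (responsive to both X and Y)
#' receive `betaY = shared_slope * betaX + Normal(0, shared_noise_sd)`, so
#' that Y effects track X effects but are smaller on average; the small
#' perturbation is redrawn for the rare genes where it would flip the sign,
#' keeping X and Y responses concordant in polarity.
#'
#' @param n_genes Number of genes.
#' @param frac_x_responsive,frac_y_responsive,frac_shared Fractions of genes
#'   responsive to X, to Y, and to both. `frac_shared` must not exceed the
#'   smaller of the other two; shared genes count towards both.
#' @param effect_sd SD (log2 units per copy) of responsive-gene effects.
#' @param shared_slope,shared_noise_sd Y-vs-X effect relation for shared genes.
#' @param frac_21_responsive Fraction of genes responding to Chr 21 dosage.
#' @param dispersion Negative binomial dispersion alpha (scalar or per gene);
#'   0 gives Poisson counts.
#' @param batches Batch labels; per-gene, per-batch offsets are drawn from
#'   `Normal(0, batch_sd)` log2 units.
#' @param batch_sd SD of batch offsets in log2 units.
#' @param frac_escape Fraction of genes escaping X inactivation.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of baseline
#'   mean expression (arbitrary units; rescaled at count generation).
#' @param seed Integer seed.
#' @return A list of class `xy_truth` with elements `genes` (data frame with
#'   columns `gene_id`, `baseline`, `beta_x`, `beta_y`, `beta_21`,
#'   `dispersion`, `responsive_x`, `responsive_y`, `shared`, `escape_status`,
#'   `xi_fraction`), `batch_effects` (gene x batch matrix, log2 units), and
#'   `params`.
#' @examples
#' truth <- generate_truth(100, 0.2, 0.1, 0.05, seed = 1)
#' sum(truth$genes$shared)  # 5
#' @export
generate_truth <- function(n_genes,
                           frac_x_responsive = 0.18,
                           frac_y_responsive = 0.06,
                           frac_shared = 0.04,
                           effect_sd = 0.2,
                           shared_slope = 0.7,
                           shared_noise_sd = 0.05,
                           frac_21_responsive = 0,
                           dispersion = 0.1,
                           batches = c("batch1", "batch2", "batch3"),
                           batch_sd = 0.1,
                           frac_escape = 0.2,
                           baseline_meanlog = log(100),
                           baseline_sdlog = 1,
                           seed = 1L) {
  fr <- c(frac_x_responsive, frac_y_responsive, frac_shared,
          frac_21_responsive, frac_escape)
  if (any(fr < 0 | fr > 1)) {
    stop("all fractions must lie in [0, 1]", call. = FALSE)
  }
  if (effect_sd <= 0) stop("`effect_sd` must be positive", call. = FALSE)
  if (frac_shared > min(frac_x_responsive, frac_y_responsive) + 1e-12) {
    stop("`frac_shared` cannot exceed min(frac_x_responsive, frac_y_responsive)",
         call. = FALSE)
  }
  n_x <- round(frac_x_responsive * n_genes)
  n_y <- round(frac_y_responsive * n_genes)
  n_sh <- round(frac_shared * n_genes)

  with_seed(seed, {
    gene_id <- sprintf("g%05d", seq_len(n_genes))
    baseline <- rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
    alpha <- rep_len(dispersion, n_genes)
    if (any(alpha < 0)) stop("`dispersion` must be >= 0", call. = FALSE)

    perm <- sample.int(n_genes)
    shared_idx <- perm[seq_len(n_sh)]
    x_only <- perm[seq_len(n_x - n_sh) + n_sh]
    y_only <- perm[seq_len(n_y - n_sh) + n_x]

    beta_x <- beta_y <- beta_21 <- numeric(n_genes)
    responsive_x <- responsive_y <- shared <- logical(n_genes)
    responsive_x[c(shared_idx, x_only)] <- TRUE
    responsive_y[c(shared_idx, y_only)] <- TRUE
    shared[shared_idx] <- TRUE

    beta_x[responsive_x] <- rnorm(sum(responsive_x), 0, effect_sd)
    beta_y[y_only] <- rnorm(length(y_only), 0, effect_sd)
    for (g in shared_idx) {
      repeat {
        by <- shared_slope * beta_x[g] + rnorm(1, 0, shared_noise_sd)
        if (sign(by) == sign(beta_x[g]) || beta_x[g] == 0) break
      }
      beta_y[g] <- by
    }

    n_21 <- round(frac_21_responsive * n_genes)
    if (n_21 > 0) {
      idx21 <- sample.int(n_genes, n_21)
      beta_21[idx21] <- rnorm(n_21, 0, effect_sd)
    }

    escape <- rep("subject", n_genes)
    escape[sample.int(n_genes, round(frac_escape * n_genes))] <- "escape"
    xi_fraction <- numeric(n_genes)
    xi_fraction[escape == "escape"] <-
      runif(sum(escape == "escape"), 0.1, 0.45)

    batch_effects <- matrix(rnorm(n_genes * length(batches), 0, batch_sd),
                            nrow = n_genes,
                            dimnames = list(gene_id, batches))

    genes <- data.frame(
      gene_id = gene_id, baseline = baseline, beta_x = beta_x,
      beta_y = beta_y, beta_21 = beta_21, dispersion = alpha,
      responsive_x = responsive_x, responsive_y = responsive_y,
      shared = shared, escape_status = escape, xi_fraction = xi_fraction,
      stringsAsFactors = FALSE
    )
    structure(
      list(genes = genes, batch_effects = batch_effects,
           params = list(effect_sd = effect_sd, shared_slope = shared_slope,
                         shared_noise_sd = shared_noise_sd,
                         batch_sd = batch_sd, seed = seed)),
      class = "xy_truth"
    )
  })
}

#' @method print xy_truth
#' @export
print.xy_truth <- function(x, ...) {
  g <- x$genes
  cat(sprintf(
    "xy_truth: %d genes (%d X-responsive, %d Y-responsive, %d shared, %d escape)\n",
    nrow(g), sum(g$responsive_x), sum(g$responsive_y), sum(g$shared),
    sum(g$escape_status == "escape")))
  invisible(x)
}
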