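#' Simulate allelic-ratio evidence in five published dialects
#'
#' Emits the five table schemas consumed by the Xi-escape meta-analysis,
#' generated from a common ground truth: genes escaping X inactivation have a
#' true allelic ratio (AR, Xi/Xa) of `xi_fraction / (1 - xi_fraction)`, and
#' subject genes have AR 0. Per-sample allele counts are drawn from a
#' beta-binomial with the stated overdispersion; setting
#' `total_reads = Inf` produces noise-free evidence (ARs exactly at their
#' expected values), which is the configuration used for exact round-trip
#' checks.
#'
#' The dialects are: `cotton` (per-gene mean AR, SD and n informative
#' samples), `tukiainen` (per-individual single-cell adjusted p values plus a
#' bulk table), `garieri` (per-sample Xa read fractions), `sauteraud`
#' (per-sample raw ARs with a skewing coefficient), `sanroman` (per-sample
#' skew-adjusted ARs), plus a `hybrid` table giving the fraction of Xi-hybrid
#' cell lines expressing each gene, used only for genes absent from all five
#' datasets.
#'
#' @param truth Ground truth from [generate_truth()] (uses `escape_status`
#'   and `xi_fraction`).
#' @param n_samples_per_dataset Samples (or individuals) per dataset; a
#'   scalar or a named vector with names `cotton`, `tukiainen`, `garieri`,
#'   `sauteraud`, `sanroman`. All values must be >= 2.
#' @param total_reads Allelic read depth per sample; `Inf` for noise-free.
#' @param overdispersion Beta-binomial intra-class correlation rho in
#'   `[0, 1)`; 0 gives binomial counts.
#' @param missing_rate Probability a gene is absent from a given dataset.
#' @param seed Integer seed.
#' @return List of class `xy_allelic` with elements `cotton`, `tukiainen`
#'   (itself a list `single_cell` + `bulk`), `garieri`, `sauteraud`,
#'   `sanroman`, `hybrid`.
#' @export
generate_allelic_datasets <- function(truth,
                                      n_samples_per_dataset = c(
                                        cotton = 8, tukiainen = 3,
                                        garieri = 5, sauteraud = 12,
                                        sanroman = 8),
                                      total_reads = 100,
                                      overdispersion = 0.02,
                                      missing_rate = 0.05,
                                      seed = 1L) {
  if (!inherits(truth, "xy_truth")) {
    stop("`truth` must come from generate_truth()", call. = FALSE)
  }
  ds <- c("cotton", "tukiainen", "garieri", "sauteraud", "sanroman")
  if (is.null(names(n_samples_per_dataset))) {
    n_samples_per_dataset <- setNames(
      rep_len(n_samples_per_dataset, 5), ds)
  }
  ns <- n_samples_per_dataset[ds]
  if (any(is.na(ns)) || any(ns < 2)) {
    stop("each dataset needs at least 2 samples", call. = FALSE)
  }
  g <- truth$genes
  phi <- ifelse(g$escape_status == "escape", g$xi_fraction, 0)
  names(phi) <- g$gene_id

  with_seed(seed, {
    keep <- function() {
      g$gene_id[runif(nrow(g)) >= missing_rate]
    }

    # cotton: aggregate mean AR / sd / n
    ids <- keep()
    ars <- lapply(ids, function(id) {
      sample_ars(phi[[id]], ns[["cotton"]], total_reads, overdispersion)
    })
    cotton <- data.frame(
      gene = ids,
      mean_ar = vapply(ars, mean, numeric(1)),
      sd_ar = vapply(ars, sd, numeric(1)),
      n = ns[["cotton"]],
      stringsAsFactors = FALSE
    )

    # tukiainen: per-individual single-cell padj + bulk
    ids <- keep()
    n_ind <- ns[["tukiainen"]]
    sc <- do.call(rbind, lapply(ids, function(id) {
      a <- sample_ars(phi[[id]], n_ind, total_reads, overdispersion)
      data.frame(gene = id, individual = paste0("ind", seq_len(n_ind)),
                 ar = a,
                 padj = ifelse(phi[[id]] > 0, runif(n_ind, 0, 0.04),
                               runif(n_ind, 0.2, 1)),
                 stringsAsFactors = FALSE)
    }))
    bulk_ids <- ids[runif(length(ids)) >= missing_rate]
    bulk <- data.frame(
      gene = bulk_ids,
      ar = vapply(bulk_ids, function(id) {
        mean(sample_ars(phi[[id]], 1, total_reads, overdispersion))
      }, numeric(1)),
      padj = ifelse(phi[bulk_ids] > 0, runif(length(bulk_ids), 0, 0.04),
                    runif(length(bulk_ids), 0.2, 1)),
      stringsAsFactors = FALSE
    )

    # garieri: per-sample Xa fractions
    ids <- keep()
    garieri <- do.call(rbind, lapply(ids, function(id) {
      a <- sample_ars(phi[[id]], ns[["garieri"]], total_reads, overdispersion)
      data.frame(gene = id, sample = paste0("f", seq_len(ns[["garieri"]])),
                 xa_fraction = 1 / (1 + a), stringsAsFactors = FALSE)
    }))

    # sauteraud: raw ARs on top of a skew-determined baseline
    ids <- keep()
    sauteraud <- do.call(rbind, lapply(ids, function(id) {
      n <- ns[["sauteraud"]]
      skew <- runif(n, 0.8, 1)
      a <- sample_ars(phi[[id]], n, total_reads, overdispersion)
      data.frame(gene = id, sample = paste0("l", seq_len(n)),
                 raw_ar = (1 - skew) / skew + a, skew = skew,
                 stringsAsFactors = FALSE)
    }))

    # sanroman: per-sample skew-adjusted ARs
    ids <- keep()
    sanroman <- do.call(rbind, lapply(ids, function(id) {
      a <- sample_ars(phi[[id]], ns[["sanroman"]], total_reads,
                      overdispersion)
      data.frame(gene = id, sample = paste0("b", seq_len(ns[["sanroman"]])),
                 ar = a, stringsAsFactors = FALSE)
    }))

    hybrid <- data.frame(
      gene = g$gene_id,
      fraction = ifelse(phi > 0, runif(nrow(g), 0.25, 0.9),
                        runif(nrow(g), 0, 0.2)),
      stringsAsFactors = FALSE
    )

    structure(list(cotton = cotton,
                   tukiainen = list(single_cell = sc, bulk = bulk),
                   garieri = garieri, sauteraud = sauteraud,
                   sanroman = sanroman, hybrid = hybrid),
              class = "xy_allelic")
  })
}

# Per-sample allelic ratios (lower/higher allele) for a gene with Xi
# expression fraction phi. Infinite read depth short-circuits to the exact
# expected AR phi/(1-phi).
sample_ars <- function(phi, n, total_reads, overdispersion) {
  if (is.infinite(total_reads)) {
    return(rep(phi / (1 - phi), n))
  }
  t <- as.integer(total_reads)
  if (phi <= 0) {
    k <- integer(n)
  } else if (overdispersion > 0) {
    r <- (1 - overdispersion) / overdispersion
    p <- rbeta(n, phi * r, (1 - phi) * r)
    k <- rbinom(n, t, p)
  } else {
    k <- rbinom(n, t, phi)
  }
  pmin(k / pmax(t - k, 1), 1)
}
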