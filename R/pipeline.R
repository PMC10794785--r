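#' Configuration for a simulation study run
#'
#' Collects every knob of the end-to-end synthetic study: the karyotype
#' design, gene-level simulation parameters, analysis thresholds and the
#' output directory. Every stochastic stage derives its seed from the
#' single `seed` here, so a configuration fully determines the run.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master integer seed.
#' @param design A [karyotype_design()].
#' @param n_genes Number of simulated genes.
#' @param frac_x_responsive,frac_y_responsive,frac_shared,effect_sd,dispersion
#'   Passed to [generate_truth()].
#' @param library_size_mean Passed to [generate_counts()].
#' @param alpha Adjusted-p threshold for calling responsive genes.
#' @param min_tpm Expression filter threshold (median TPM).
#' @param counts_path Optional path to a counts TSV to analyse instead of
#'   simulating; must exist if given.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, design = lcl_design(),
                       n_genes = 2000, frac_x_responsive = 0.18,
                       frac_y_responsive = 0.06, frac_shared = 0.04,
                       effect_sd = 0.2, dispersion = 0.1,
                       library_size_mean = 2e5, alpha = 0.05, min_tpm = 1,
                       counts_path = NULL) {
  stopifnot(alpha > 0, min_tpm > 0)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 design = design, n_genes = n_genes,
                 frac_x_responsive = frac_x_responsive,
                 frac_y_responsive = frac_y_responsive,
                 frac_shared = frac_shared, effect_sd = effect_sd,
                 dispersion = dispersion,
                 library_size_mean = library_size_mean, alpha = alpha,
                 min_tpm = min_tpm, counts_path = counts_path),
            class = "run_config")
}

#' Run the simulation study end to end
#'
#' Executes generate -> normalize/filter -> fit -> shared-response
#' comparison -> report on a [run_config()], writing every intermediate
#' table and a JSON manifest (configuration echo, versions, seeds, per-stage
#' row counts, thresholds applied, output checksums) to the configured
#' output directory. Reruns with the same configuration are bit-identical.
#' A stage failure aborts the run with the stage name.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the manifest and the in-memory results
#'   (`meta`, `truth`, `counts`, `fits`, `shared`).
#' @export
run_simulation_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$counts_path) && !file.exists(config$counts_path)) {
    stop(sprintf("counts path does not exist: %s", config$counts_path),
         call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  rowcounts <- list()
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    stages <<- c(stages, name)
    res
  }

  annotation <- NULL
  meta <- run_stage("design", generate_design(config$design,
                                              seed = config$seed))
  truth <- run_stage("truth", generate_truth(
    config$n_genes, config$frac_x_responsive, config$frac_y_responsive,
    config$frac_shared, effect_sd = config$effect_sd,
    dispersion = config$dispersion,
    batches = attr(config$design, "batches"), seed = config$seed + 1L))
  counts <- run_stage("counts", {
    annotation <- generate_annotation(truth$genes$gene_id,
                                      seed = config$seed + 3L)
    if (is.null(config$counts_path)) {
      generate_counts(meta, truth,
                      library_size_mean = config$library_size_mean,
                      seed = config$seed + 2L)
    } else {
      read_counts_tsv(config$counts_path)
    }
  })

  expressed <- run_stage("filter", {
    tpm <- compute_tpm(counts, setNames(annotation$length,
                                        annotation$gene_id))
    filter_expressed(tpm, meta, min_tpm = config$min_tpm)
  })

  fits <- run_stage("fit", fit_dosage_glm(
    counts, meta,
    design_spec(c("x_count", "y_count"), "batch",
                c("x_count", "y_count")),
    genes = expressed))

  shared <- run_stage("shared", {
    fx <- fits[fits$coef == "x_count", ]
    fy <- fits[fits$coef == "y_count", ]
    sig_x <- fx$gene[!is.na(fx$padj) & fx$padj < config$alpha]
    sig_y <- fy$gene[!is.na(fy$padj) & fy$padj < config$alpha]
    both <- intersect(sig_x, sig_y)
    ov <- overlap_test(sig_x, sig_y, expressed)
    res <- data.frame(
      statistic = c("n_expressed", "n_sig_x", "n_sig_y", "n_shared",
                    "overlap_p"),
      value = c(length(expressed), length(sig_x), length(sig_y),
                length(both), ov$p_value), stringsAsFactors = FALSE)
    if (length(both) >= 3) {
      ce <- correlate_effects(fx, fy, both)
      dm <- weighted_deming(
        setNames(fx$log2fc_per_copy, fx$gene)[both],
        setNames(fy$log2fc_per_copy, fy$gene)[both],
        xstd = setNames(fx$se, fx$gene)[both],
        ystd = setNames(fy$se, fy$gene)[both])
      res <- rbind(res, data.frame(
        statistic = c("pearson_r_shared", "deming_slope_y_vs_x"),
        value = c(ce$r, dm$slope), stringsAsFactors = FALSE))
    }
    res
  })

  paths <- c(meta = "meta.tsv", truth = "truth.tsv", counts = "counts.tsv",
             annotation = "annotation.tsv", fits = "fits.tsv",
             shared = "shared.tsv")
  paths <- vapply(paths, function(p) file.path(config$out_dir, p),
                  character(1))
  write_table_tsv(meta, paths["meta"])
  write_table_tsv(truth$genes, paths["truth"])
  write_counts_tsv(counts, paths["counts"])
  write_table_tsv(annotation, paths["annotation"])
  write_table_tsv(fits, paths["fits"])
  write_table_tsv(shared, paths["shared"])

  rowcounts <- list(design = nrow(meta), truth = nrow(truth$genes),
                    counts = nrow(counts), annotation = nrow(annotation),
                    filter = length(expressed), fit = nrow(fits),
                    shared = nrow(shared))
  run_stage("report", TRUE)
  manifest <- list(
    package = "xydosage",
    package_version = as.character(utils::packageVersion("xydosage")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    stage_seeds = list(design = config$seed, truth = config$seed + 1L,
                       counts = config$seed + 2L,
                       annotation = config$seed + 3L),
    thresholds = list(alpha = config$alpha, min_tpm = config$min_tpm,
                      padjust_method = "BH",
                      padjust_denominator = length(expressed)),
    config = config[setdiff(names(config), "design")],
    karyotypes = as.list(setNames(config$design$n,
                                  config$design$karyotype)),
    stages_completed = stages,
    row_counts = rowcounts,
    checksums = as.list(tools::md5sum(unname(paths))))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(manifest = manifest, meta = meta, truth = truth,
                 counts = counts, fits = fits, shared = shared,
                 expressed = expressed))
}
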