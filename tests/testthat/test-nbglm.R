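test_that("a constant gene fits a null effect", {
  meta <- generate_design(
    karyotype_design(c("45,X", "46,XX", "46,XY"), c(4, 4, 4),
                     batches = "b1"), seed = 1)
  counts <- matrix(50, nrow = 5, ncol = 12,
                   dimnames = list(sprintf("g%d", 1:5), meta$sample_id))
  fit <- fit_dosage_glm(counts, meta,
                        design_spec(c("x_count", "y_count"),
                                    coefficients = c("x_count", "y_count")))
  expect_true(all(abs(fit$log2fc_per_copy) < 1e-6))
  expect_true(all(fit$p > 0.9))
  expect_true(all(fit$converged))
})

test_that("estimates recover simulated per-copy effects", {
  s <- small_study()
  fit <- small_fit()
  fx <- fit[fit$coef == "x_count", ]
  g <- s$truth$genes
  est <- fx$log2fc_per_copy[match(g$gene_id, fx$gene)]
  resp <- g$responsive_x
  expect_lt(median(abs(est[resp] - g$beta_x[resp])), 0.05)
  expect_gt(cor(est[resp], g$beta_x[resp]), 0.95)
  # a strong single gene is individually pinned down
  strong <- which.max(abs(g$beta_x))
  expect_lt(abs(est[strong] - g$beta_x[strong]), 0.1)
})

test_that("NB fit agrees with a log-linear least-squares oracle on Poisson data", {
  meta <- generate_design(
    karyotype_design(c("45,X", "46,XX", "47,XXX"), c(30, 30, 30),
                     batches = "b1"), seed = 2)
  truth <- generate_truth(40, 0.5, 0, 0, dispersion = 0, batches = "b1",
                          baseline_meanlog = log(3000),
                          baseline_sdlog = 0.2, seed = 3)
  counts <- generate_counts(meta, truth, library_size_mean = 5e6,
                            library_size_sd = 0, seed = 4)
  fit <- fit_dosage_glm(counts, meta,
                        design_spec("x_count", coefficients = "x_count"),
                        dispersion = 0)
  sf <- size_factors(counts)$factors
  oracle <- apply(counts, 1, function(y) {
    coef(lm(log2(y / sf) ~ meta$x_count))[2]
  })
  est <- fit$log2fc_per_copy[match(names(oracle), fit$gene)]
  expect_true(all(abs(est - oracle) < 0.02))
})

test_that("estimates are invariant to count scaling and covariate centering", {
  s <- small_study()
  ds <- s$design
  base <- fit_dosage_glm(s$counts, s$meta, ds, dispersion = 0)
  # a global depth change is absorbed exactly by the size factors
  global <- fit_dosage_glm(s$counts * 5, s$meta, ds, dispersion = 0)
  expect_true(all(abs(base$log2fc_per_copy - global$log2fc_per_copy) < 1e-6))
  # tripling one sample's counts is absorbed by its size factor; under the
  # NB weights the estimates stay stable
  counts2 <- s$counts
  counts2[, 1] <- counts2[, 1] * 3
  base_nb <- fit_dosage_glm(s$counts, s$meta, ds)
  scaled_nb <- fit_dosage_glm(counts2, s$meta, ds)
  expect_lt(max(abs(base_nb$log2fc_per_copy - scaled_nb$log2fc_per_copy)),
            0.01)

  meta_c <- s$meta
  meta_c$x_count <- meta_c$x_count - mean(meta_c$x_count)
  meta_c$y_count <- meta_c$y_count - mean(meta_c$y_count)
  centred <- fit_dosage_glm(s$counts, meta_c, ds, dispersion = 0)
  expect_true(all(abs(base$log2fc_per_copy - centred$log2fc_per_copy) < 1e-6))
})

test_that("BH adjustment is monotone and bounded within each coefficient", {
  fit <- small_fit()
  for (cf in unique(fit$coef)) {
    sub <- fit[fit$coef == cf & fit$converged, ]
    expect_true(all(sub$padj >= sub$p - 1e-12))
    expect_true(all(sub$padj <= 1))
    # sorting by p and by adjusted p yields the same ordering
    expect_true(all(diff(sub$padj[order(sub$p)]) >= -1e-12))
  }
})

test_that("degenerate designs are rejected before fitting", {
  s <- small_study()
  meta <- s$meta
  meta$x_copy <- meta$x_count
  expect_error(
    fit_dosage_glm(s$counts, meta,
                   design_spec(c("x_count", "x_copy"),
                               coefficients = "x_count")),
    "rank deficient")
  one_k <- meta[meta$karyotype == "46,XX", ]
  expect_error(
    fit_dosage_glm(s$counts[, one_k$sample_id], one_k,
                   design_spec("x_count", coefficients = "x_count")),
    "no variation")
  expect_error(
    fit_dosage_glm(s$counts, meta,
                   design_spec("x_count", coefficients = "nope")),
    "nope")
})

test_that("fits agree with DESeq2 as an independent oracle", {
  meta <- generate_design(
    karyotype_design(c("45,X", "46,XX", "46,XY", "47,XXY", "47,XXX"),
                     c(10, 10, 10, 10, 10)), seed = 8)
  truth <- generate_truth(150, 0.3, 0.1, 0.05, seed = 9)
  counts <- generate_counts(meta, truth, library_size_mean = 2e5,
                            seed = 10)
  fit <- fit_dosage_glm(
    counts, meta,
    design_spec(c("x_count", "y_count"), "batch", "x_count"))
  storage.mode(counts) <- "integer"
  cd <- data.frame(x_count = meta$x_count, y_count = meta$y_count,
                   batch = factor(meta$batch))
  dds <- suppressMessages(DESeq2::DESeqDataSetFromMatrix(
    counts, cd, ~ x_count + y_count + batch))
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds, name = "x_count")
  mine <- fit$log2fc_per_copy[match(rownames(res), fit$gene)]
  ok <- is.finite(res$log2FoldChange)
  expect_gt(cor(mine[ok], res$log2FoldChange[ok]), 0.98)
  expect_lt(median(abs(mine[ok] - res$log2FoldChange[ok])), 0.05)
})

test_that("alternative designs recover trisomy-21 and knockdown effects", {
  # trisomy-21 design: chr21 copies with sex constitution and batch
  meta <- generate_design(
    karyotype_design(c("46,XX", "46,XY", "47,XX+21", "47,XY+21"),
                     c(24, 24, 24, 24)), seed = 11)
  truth <- generate_truth(150, 0, 0, 0, frac_21_responsive = 0.3,
                          seed = 12)
  counts <- generate_counts(meta, truth, library_size_mean = 5e5,
                            seed = 13)
  meta$sex <- ifelse(meta$y_count > 0, "XY", "XX")
  fit <- fit_dosage_glm(
    counts, meta,
    design_spec("chr21_count", c("sex", "batch"), "chr21_count"))
  g <- truth$genes
  est <- fit$log2fc_per_copy[match(g$gene_id, fit$gene)]
  resp <- g$beta_21 != 0
  expect_lt(median(abs(est[resp] - g$beta_21[resp])), 0.1)

  # knockdown design: an 80% reduction is recovered as log2(0.2)
  kmeta <- data.frame(
    sample_id = sprintf("k%02d", 1:18),
    target = factor(rep(c("control", "ZFX", "ZFY"), each = 6),
                    levels = c("control", "ZFX", "ZFY")),
    line = rep(sprintf("line%d", 1:3), 6), stringsAsFactors = FALSE)
  ktruth <- generate_truth(60, 0, 0, 0, dispersion = 0.02, batches = "b1",
                           baseline_meanlog = log(500), seed = 14)
  kcounts <- local({
    mu <- ktruth$genes$baseline / sum(ktruth$genes$baseline) * 3e5
    m <- matrix(0, 60, 18, dimnames = list(ktruth$genes$gene_id,
                                           kmeta$sample_id))
    set.seed(15)
    for (j in 1:18) {
      mj <- mu
      if (kmeta$target[j] == "ZFX") mj[1] <- mj[1] * 0.2
      m[, j] <- rnbinom(60, mu = mj, size = 50)
    }
    m
  })
  kfit <- fit_dosage_glm(
    kcounts, kmeta,
    design_spec(categorical = c("target", "line"),
                coefficients = c("targetZFX", "targetZFY")))
  own <- kfit[kfit$gene == ktruth$genes$gene_id[1] &
                kfit$coef == "targetZFX", ]
  expect_equal(own$log2fc_per_copy, log2(0.2), tolerance = 0.25)
  expect_lt(own$padj, 0.05)
})
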