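test_that("allelic ratio conversions are exact and mutually inverse", {
  expect_equal(round(ar_from_xa_fraction(0.95), 4), 0.0526)
  expect_equal(ar_from_xa_fraction(1), 0)
  expect_equal(ar_from_xa_fraction(0.5), 1)
  expect_error(ar_from_xa_fraction(0), "0, 1")
  expect_error(ar_from_xa_fraction(1.2), "0, 1")
  f <- seq(0.01, 1, by = 0.01)
  expect_true(all(abs(xa_fraction_from_ar(ar_from_xa_fraction(f)) - f)
                  < 1e-12))
  expect_equal(baseline_ar(1), 0)
  expect_equal(baseline_ar(0.9), 1 / 9)
  expect_equal(baseline_ar(0.5), 1)
  expect_error(baseline_ar(0.3), "0.5")
})

test_that("the aggregate-AR caller applies inclusion, testing and degeneracy rules", {
  null_genes <- data.frame(gene = sprintf("n%03d", 1:100),
                           mean_ar = 0, sd_ar = 0.05, n = 10)
  d <- rbind(null_genes,
             data.frame(gene = "esc", mean_ar = 0.3, sd_ar = 0.05, n = 10),
             data.frame(gene = "thin", mean_ar = 0.3, sd_ar = 0.05, n = 4),
             data.frame(gene = "degen", mean_ar = 0.2, sd_ar = 0, n = 8))
  res <- call_cotton(d)
  expect_equal(res$call[res$gene == "esc"], "escape")
  expect_equal(res$call[res$gene == "thin"], "no_data")
  expect_equal(res$call[res$gene == "degen"], "escape")
  expect_equal(res$flag[res$gene == "degen"], "degenerate_positive")
  expect_true(all(res$call[grepl("^n", res$gene)] == "subject"))
})

test_that("the single-cell-plus-bulk caller follows the inclusion matrix", {
  sc <- data.frame(
    gene = c("only1", "two_a", "two_a", "two_b", "two_b", "with_bulk"),
    individual = c("i1", "i1", "i2", "i1", "i2", "i1"),
    ar = c(0.2, 0.2, 0.01, 0.01, 0.02, 0.3),
    padj = c(0.01, 0.01, 0.5, 0.5, 0.6, 0.2))
  bulk <- data.frame(gene = c("with_bulk", "bulk_only"),
                     ar = c(0.3, 0.1), padj = c(0.01, 0.3))
  res <- call_tukiainen(sc, bulk)
  expect_equal(res$call[res$gene == "only1"], "no_data")
  expect_equal(res$call[res$gene == "two_a"], "escape")
  expect_equal(res$call[res$gene == "two_b"], "subject")
  expect_equal(res$call[res$gene == "with_bulk"], "escape")
  expect_equal(res$call[res$gene == "bulk_only"], "no_data")
})

test_that("the per-sample threshold caller uses the 0.0526 cutoff", {
  d <- data.frame(gene = rep(c("sub", "esc", "one"), c(2, 2, 1)),
                  sample = c("s1", "s2", "s1", "s2", "s1"),
                  ar = c(0.01, 0.02, 0.01, 0.06, 0.9))
  res <- call_garieri(d)
  expect_equal(res$call[res$gene == "sub"], "subject")
  expect_equal(res$call[res$gene == "esc"], "escape")
  expect_equal(res$call[res$gene == "one"], "no_data")
  # xa-fraction input converts through AR = 1/f - 1
  d2 <- data.frame(gene = rep("g", 2), sample = c("s1", "s2"),
                   xa_fraction = c(0.96, 0.94))
  expect_equal(call_garieri(d2)$call, "escape")
})

test_that("the skew-baseline caller tests raw AR above baseline", {
  skew <- runif(12, 0.8, 0.95)
  base <- (1 - skew) / skew
  at_base <- data.frame(gene = "null", sample = seq_len(12),
                        raw_ar = base, skew = skew)
  above <- data.frame(gene = "esc", sample = seq_len(12),
                      raw_ar = base + 0.2, skew = skew)
  thin <- data.frame(gene = "thin", sample = seq_len(9),
                     raw_ar = base[1:9] + 0.2, skew = skew[1:9])
  res <- call_sauteraud(rbind(at_base, above, thin))
  expect_equal(res$call[res$gene == "null"], "subject")
  expect_equal(res$flag[res$gene == "null"], "zero_variance")
  expect_equal(res$call[res$gene == "esc"], "escape")
  expect_equal(res$call[res$gene == "thin"], "no_data")
})

test_that("the per-sample t-test caller handles null, strong and single-sample genes", {
  set.seed(51)
  null_d <- data.frame(gene = rep(sprintf("n%02d", 1:50), each = 8),
                       ar = 0)
  esc_d <- data.frame(gene = rep("esc", 8), ar = rnorm(8, 0.3, 0.02))
  one_d <- data.frame(gene = "one", ar = 0.5)
  res <- call_sanroman(rbind(null_d, esc_d, one_d))
  expect_true(all(res$call[grepl("^n", res$gene)] == "subject"))
  expect_equal(res$call[res$gene == "esc"], "escape")
  expect_equal(res$call[res$gene == "one"], "no_data")
})

test_that("call synthesis matches the documented rule walk-through", {
  mk <- function(calls, ars) {
    data.frame(gene = "g", dataset = paste0("d", seq_along(calls)),
               call = calls, mean_ar = ars)
  }
  final <- function(calls, ars, hybrid = NULL) {
    h <- if (is.null(hybrid)) NULL else data.frame(gene = "g",
                                                   fraction = hybrid)
    synthesize_calls(mk(calls, ars), h)$final
  }
  # 3 of 5 escape -> escape (majority)
  expect_equal(final(rep(c("escape", "subject"), c(3, 2)), rep(0.2, 5)),
               "escape")
  # 1 of 5 escape with average AR 0.15 -> escape (AR clause)
  expect_equal(final(rep(c("escape", "subject"), c(1, 4)), rep(0.15, 5)),
               "escape")
  # 2 of 5 escape, low AR -> escape (>1 escape study clause)
  expect_equal(final(rep(c("escape", "subject"), c(2, 3)), rep(0.05, 5)),
               "escape")
  # 1 of 2 escape, average AR 0.08 -> no_call (fails both clause sets)
  expect_equal(final(c("escape", "subject"), c(0.08, 0.08)), "no_call")
  # all informative subject -> subject (unanimity)
  expect_equal(final(rep("subject", 4), rep(0.02, 4)), "subject")
  # no informative data: hybrid rule at the 22% boundary
  expect_equal(final(rep("no_data", 5), rep(NA, 5), hybrid = 0.30),
               "escape")
  expect_equal(final(rep("no_data", 5), rep(NA, 5), hybrid = 0.22),
               "escape")
  expect_equal(final(rep("no_data", 5), rep(NA, 5), hybrid = 0.10),
               "subject")
  expect_equal(final(rep("no_data", 5), rep(NA, 5)), "no_call")
})

test_that("call synthesis agrees with the decision table over an exhaustive grid", {
  for (n_e in 0:5) for (n_s in 0:(5 - n_e)) {
    for (avg in c(0.05, 0.15)) for (h in c(NA, 0.1, 0.3)) {
      calls <- data.frame(
        gene = "g",
        dataset = paste0("d", seq_len(max(n_e + n_s, 1))),
        call = if (n_e + n_s == 0) "no_data" else
          rep(c("escape", "subject"), c(n_e, n_s)),
        mean_ar = if (n_e + n_s == 0) NA_real_ else avg)
      hyb <- if (is.na(h)) NULL else data.frame(gene = "g", fraction = h)
      got <- synthesize_calls(calls, hyb)$final
      expect_identical(got, expected_final_call(n_e, n_s, avg, h),
                       label = sprintf("nE=%d nS=%d avg=%.2f h=%s -> %s",
                                       n_e, n_s, avg, h, got))
    }
  }
})

test_that("noise-free synthetic evidence round-trips through the meta-analysis", {
  truth <- generate_truth(150, 0.1, 0.05, 0.02, frac_escape = 0.3,
                          seed = 55)
  ad <- generate_allelic_datasets(truth, total_reads = Inf, seed = 56)
  res <- escape_meta(ad)
  truthcall <- setNames(truth$genes$escape_status, truth$genes$gene_id)
  expect_true(all(res$final == truthcall[res$gene]))
})
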