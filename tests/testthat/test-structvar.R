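test_that("GC correction is identity for uniform GC and preserves zeros", {
  prof <- data.frame(gc = rep(0.45, 40), depth = c(rep(2, 20), rep(400, 20)),
                     region = rep(c("single_copy", "repeat"), each = 20))
  corr <- gc_correct(prof)
  expect_equal(corr$depth, prof$depth)
  zeros <- data.frame(gc = runif(30), depth = 0,
                      region = rep(c("single_copy", "repeat"), 15))
  expect_equal(gc_correct(zeros)$depth, rep(0, 30))
  expect_error(gc_correct(data.frame(gc = 0.4, depth = 1,
                                     region = "repeat")), "single-copy")
})

test_that("GC correction removes the simulated bias", {
  prof <- generate_depth_profile(200, gc_bias_strength = 3,
                                 n_windows = 300, seed = 61)
  corr <- gc_correct(prof)
  sc <- corr[corr$region == "single_copy", ]
  raw_rho <- cor(sc$gc, sc$depth_raw, method = "spearman")
  rho <- cor(sc$gc, sc$depth, method = "spearman")
  expect_gt(abs(raw_rho), 0.5)
  expect_lt(abs(rho), 0.1)
})

test_that("normalized repeat depth is a scale-invariant ratio", {
  prof <- data.frame(gc = rep(0.4, 20),
                     depth = c(rep(2, 10), rep(400, 10)),
                     region = rep(c("single_copy", "repeat"), each = 10))
  expect_equal(normalized_repeat_depth(prof), 200)
  scaled <- prof; scaled$depth <- scaled$depth * 7.3
  expect_equal(normalized_repeat_depth(scaled), 200)
  same <- prof; same$depth <- rep(3, 20)
  expect_equal(normalized_repeat_depth(same), 1)
  bad <- prof; bad$depth[bad$region == "single_copy"] <- 0
  expect_error(normalized_repeat_depth(bad), "positive")
})

test_that("the full depth chain recovers generating repeat factors within 5%", {
  for (fac in c(24, 200, 900)) {
    for (bias in c(0, 2)) {
      prof <- generate_depth_profile(fac, gc_bias_strength = bias,
                                     n_windows = 150,
                                     seed = 62 + fac + bias)
      est <- normalized_repeat_depth(gc_correct(prof))
      expect_lt(abs(est - fac) / fac, 0.05)
    }
  }
})

test_that("the log transform and batch removal behave on constructed cases", {
  expect_equal(vst_log(c(0, 1, 3)), c(0, 1, 2))
  expect_error(vst_log(-1), "non-negative")

  m <- matrix(rnorm(60, 8), nrow = 6,
              dimnames = list(sprintf("g%d", 1:6), sprintf("s%d", 1:10)))
  expect_warning(same <- remove_batch(m, rep("b1", 10)), "fewer than two")
  expect_identical(same, m)
  shifted <- m
  shifted[, 6:10] <- shifted[, 6:10] + 2
  fixed <- remove_batch(shifted, rep(c("b1", "b2"), each = 5))
  centred <- remove_batch(m, rep(c("b1", "b2"), each = 5))
  # the +2 batch shift is eliminated; only the grand mean moves (+1)
  expect_equal(fixed, centred + 1)
  expect_equal(rowMeans(fixed[, 1:5]), rowMeans(fixed[, 6:10]))
  # within-batch contrasts survive untouched
  expect_equal(fixed[, 2] - fixed[, 1], m[, 2] - m[, 1])
})

test_that("PCA separates karyotype groups and is deterministic", {
  set.seed(63)
  m <- cbind(matrix(rnorm(50 * 8, 0), 50, 8),
             matrix(rnorm(50 * 8, 3), 50, 8))
  dimnames(m) <- list(sprintf("g%d", 1:50), sprintf("s%d", 1:16))
  pca <- pca_project(m)
  groups <- rep(c("a", "b"), each = 8)
  # silhouette on PC1
  sil <- vapply(1:16, function(i) {
    own <- abs(pca$scores[i, 1] - pca$scores[groups == groups[i], 1])
    a <- mean(own[own > 0])
    b <- mean(abs(pca$scores[i, 1] - pca$scores[groups != groups[i], 1]))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
  expect_equal(unname(crossprod(pca$loadings)), diag(2), tolerance = 1e-8)
  expect_true(all(pca$explained >= 0) && sum(pca$explained) <= 1 + 1e-12)

  dup <- cbind(m, dup = m[, 1])
  pd <- pca_project(dup)
  expect_equal(unname(pd$scores["dup", ]), unname(pd$scores["s1", ]))

  reord <- pca_project(m[rev(rownames(m)), rev(colnames(m))])
  expect_equal(pca$scores[colnames(m), ], reord$scores[colnames(m), ],
               tolerance = 1e-8)
  const <- matrix(1, 5, 5, dimnames = list(sprintf("g%d", 1:5),
                                           sprintf("s%d", 1:5)))
  expect_error(pca_project(const), "constant")
})

test_that("centroid ellipses follow the chi-square construction", {
  set.seed(64)
  scores <- matrix(rnorm(200), ncol = 2,
                   dimnames = list(sprintf("s%d", 1:100), NULL))
  ell <- centroid_ellipses(scores, rep("g", 100))
  # isotropic unit variance, n=100: semi-axes near sqrt(5.991/100)
  expect_equal(ell$semi_major, sqrt(qchisq(0.95, 2) / 100),
               tolerance = 0.2)
  expect_equal(ell$semi_minor, sqrt(qchisq(0.95, 2) / 100),
               tolerance = 0.2)
  shifted <- centroid_ellipses(scores + 5, rep("g", 100))
  expect_equal(shifted$center_x, ell$center_x + 5)
  expect_equal(shifted$semi_major, ell$semi_major)
  # groups below the size threshold get no ellipse
  two <- centroid_ellipses(scores[1:5, ], c("a", "a", "b", "b", "b"))
  expect_false("a" %in% two$group)
  expect_true("b" %in% two$group)
})

test_that("variant samples classify with the matching dosage group", {
  # Y-dosage series 0/1/2 plus a doubled-Y structural variant
  design <- karyotype_design(c("45,X", "46,XY", "47,XYY"), c(8, 8, 8),
                             batches = "b1")
  meta <- generate_design(design, seed = 65)
  truth <- generate_truth(200, 0, 0.4, 0, effect_sd = 0.4, batches = "b1",
                          seed = 66)
  variant <- data.frame(sample_id = "variant1", karyotype = "46,X,iYp",
                        x_count = 1L, y_count = 2L, xi_count = 0L,
                        chr21_count = 2L, batch = "b1",
                        cell_type = "LCL", stringsAsFactors = FALSE)
  all_meta <- rbind(meta, variant)
  counts <- generate_counts(all_meta, truth, library_size_mean = 2e5,
                            seed = 67)
  sf <- size_factors(counts)$factors
  expr <- vst_log(sweep(counts, 2, sf, "/"))
  resp <- truth$genes$gene_id[truth$genes$responsive_y]
  pca <- pca_project(expr, genes = resp)
  ref <- meta$sample_id
  centroids <- group_centroids(pca$scores[ref, ], meta$karyotype)
  cls <- classify_variant(pca$scores["variant1", , drop = FALSE], centroids)
  expect_equal(cls$label, "47,XYY")

  # coincident sample and tie handling
  ctr <- rbind(a = c(0, 0), b = c(2, 0))
  at <- classify_variant(matrix(c(0, 0), 1, dimnames = list("s", NULL)),
                         ctr)
  expect_equal(at$label, "a")
  expect_equal(at$distance, 0)
  tie <- classify_variant(matrix(c(1, 0), 1, dimnames = list("s", NULL)),
                          ctr)
  expect_equal(tie$label, "a")
  expect_true(tie$tie)
  expect_error(classify_variant(matrix(0, 1, 2), ctr[1, , drop = FALSE]),
               "2 reference")
})
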