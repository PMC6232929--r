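test_that("PCA is reproducible and captures the dominant contrast", {
  # two perfectly anti-correlated genes among constants: PC1 carries all
  # of the non-zero variance
  v <- cbind(g1 = c(0, 1, 0, 1), g2 = c(1, 0, 1, 0), g3 = 1, g4 = 0.5)
  rownames(v) <- paste0("c", 1:4)
  p <- run_pca(toy_expr(v), n_components = 2)
  expect_equal(p$explained_variance[1], 1)
  # duplicating every cell leaves each duplicate pair at the same embedding
  v2 <- rbind(v, v)
  rownames(v2) <- paste0("c", 1:8)
  p2 <- run_pca(toy_expr(v2), n_components = 2)
  expect_equal(unname(p2$scores[1:4, ]), unname(p2$scores[5:8, ]))
  expect_error(run_pca(toy_expr(v), n_components = 5),
               class = "otoctant_dim_error")

  # synthetic two-identity data: PC1 separates the ground-truth identities
  st <- generate_study(generator_spec(rng_seed = 3))
  pre <- preprocess(st$ct)
  p3 <- run_pca(pre$expr, 2)
  tr <- st$truth[match(rownames(pre$expr$values), st$truth$cell_id), ]
  nb <- tr$identity == "neuroblast"
  x <- p3$scores[, 1]
  auc <- (mean(rank(x)[nb]) - (sum(nb) + 1) / 2) / sum(!nb)
  expect_gte(max(auc, 1 - auc), 0.95)
})

test_that("clustering recovers separable structure deterministically", {
  set.seed(10)
  blobs <- rbind(matrix(rnorm(40, 0, 0.05), 20, 2),
                 matrix(rnorm(40, 5, 0.05), 20, 2))
  rownames(blobs) <- paste0("c", 1:40)
  e <- toy_expr(blobs)
  cl <- cluster_cells(e, k = 2, seed = 1)
  expect_equal(length(unique(cl$kmeans[1:20])), 1L)
  expect_equal(length(unique(cl$kmeans[21:40])), 1L)
  expect_false(cl$kmeans[1] == cl$kmeans[21])
  expect_equal(cl$agreement, 1)  # hclust agrees on separable blobs
  cl2 <- cluster_cells(e, k = 2, seed = 1)
  expect_identical(cl$kmeans, cl2$kmeans)
  expect_error(cluster_cells(e, k = 2), class = "otoctant_config_error")
  expect_error(cluster_cells(e, k = 50, seed = 1),
               class = "otoctant_dim_error")

  # generator defaults: k-means labels match ground-truth identity
  st <- generate_study(generator_spec(rng_seed = 8))
  pre <- preprocess(st$ct)
  cl3 <- cluster_cells(pre$expr, k = 2, seed = 8)
  tr <- st$truth[match(rownames(pre$expr$values), st$truth$cell_id), ]
  expect_gte(mclust::adjustedRandIndex(cl3$kmeans, tr$identity), 0.8)
})

test_that("marker scores label clusters and swap with swapped panels", {
  v <- cbind(Neurod1 = c(0.8, 0.9, 0.1, 0.0), Tubb3 = c(0.7, 0.8, 0.1, 0.2),
             Oc90 = c(0.1, 0.0, 0.9, 0.8), Lfng = c(0.2, 0.1, 0.8, 0.9))
  rownames(v) <- paste0("c", 1:4)
  e <- toy_expr(v)
  clusters <- setNames(c(1L, 1L, 2L, 2L), rownames(v))
  res <- label_clusters(clusters, e)
  expect_identical(res$cells$identity, c("neuroblast", "neuroblast",
                                         "otic_epithelial",
                                         "otic_epithelial"))
  swapped <- label_clusters(clusters, e,
                            neuro_markers = c("Oc90", "Lfng"),
                            epi_markers = c("Neurod1", "Tubb3"))
  expect_identical(swapped$cells$identity,
                   ifelse(res$cells$identity == "neuroblast",
                          "otic_epithelial", "neuroblast"))
  expect_error(label_clusters(clusters, e, neuro_markers = "Nope"),
               class = "otoctant_config_error")
  expect_error(label_clusters(setNames(rep(1L, 4), rownames(v)), e),
               class = "otoctant_labeling_error")

  # identity labels are invariant to cell and gene permutations
  st <- generate_study(generator_spec(rng_seed = 4, cells_per_embryo = 20))
  pre <- preprocess(st$ct)
  cl <- cluster_cells(pre$expr, k = 2, seed = 4)
  base <- label_clusters(cl$kmeans, pre$expr)
  perm <- pre$expr
  gp <- sample(ncol(perm$values))
  cp <- sample(nrow(perm$values))
  perm$values <- perm$values[cp, gp]
  perm$detection <- perm$detection[cp, gp]
  perm$meta <- perm$meta[cp, ]
  permuted <- label_clusters(cl$kmeans[cp], perm)
  m <- merge(base$cells, permuted$cells, by = "cell_id")
  expect_identical(m$identity.x, m$identity.y)

  # generator defaults: labeled identity matches ground truth for >= 95%
  st2 <- generate_study(generator_spec(rng_seed = 5))
  pre2 <- preprocess(st2$ct)
  cl2 <- cluster_cells(pre2$expr, k = 2, seed = 5)
  lab <- label_clusters(cl2$kmeans, pre2$expr)
  tr <- st2$truth[match(lab$cells$cell_id, st2$truth$cell_id), ]
  expect_gte(mean(lab$cells$identity == tr$identity), 0.95)
})

test_that("Welch test matches its closed form and handles degenerate input", {
  o <- welch_oracle(c(0.1, 0.2), c(0.4, 0.5))
  w <- welch_test(c(0.1, 0.2), c(0.4, 0.5))
  expect_equal(w$t, o$t, tolerance = 1e-12)
  expect_equal(w$df, o$df, tolerance = 1e-12)
  expect_equal(w$p, o$p, tolerance = 1e-12)
  expect_equal(o$df, 2)  # equal group variances, n1 = n2 = 2

  set.seed(3)
  for (i in 1:50) {
    x <- rnorm(sample(2:20, 1)); y <- rnorm(sample(2:20, 1), 0.3)
    w <- welch_test(x, y); o <- welch_oracle(x, y)
    expect_lt(abs(w$p - o$p), 1e-10)
    expect_lt(abs(w$t - o$t), 1e-10)
  }
  expect_equal(welch_test(c(1, 1, 1), c(1, 1, 1)), list(t = 0, df = 4, p = 1))
})

test_that("embryo-level fractions aggregate exactly and power the contrast", {
  st <- generate_study(generator_spec(rng_seed = 6))
  pre <- preprocess(st$ct)
  res <- classify_cells(pre$expr, seed = 6)
  fr <- res$fraction_test$fractions
  expect_true(all(fr$fraction >= 0 & fr$fraction <= 1))
  # pooled genotype fraction is the cell-count-weighted mean of embryo
  # fractions (exact identity)
  for (g in c("wildtype", "mutant")) {
    sub <- fr[fr$genotype == g, ]
    pooled <- sum(sub$n_neuroblast) / sum(sub$n)
    expect_equal(sum(sub$fraction * sub$n) / sum(sub$n), pooled)
  }
  expect_lt(res$fraction_test$test$p, 0.05)
  expect_gt(res$fraction_test$test$mean_mutant,
            res$fraction_test$test$mean_wildtype)

  ident <- res$identity
  one_embryo <- pre$expr$meta
  one_embryo$embryo_id <- ifelse(one_embryo$genotype == "wildtype",
                                 "WT1", one_embryo$embryo_id)
  expect_error(neuroblast_fraction_test(ident, one_embryo),
               class = "otoctant_test_error")
})

test_that("identical fraction groups give t = 0, p = 1", {
  cells <- sprintf("c%d", 1:70)
  meta <- toy_meta(cells,
                   embryo = rep(c("WT1", "WT2", "WT3", "MT1", "MT2",
                                  "MT3", "MT4"), each = 10),
                   genotype = rep(c("wildtype", "mutant"), c(30, 40)))
  ident <- structure(list(cells = data.frame(
    cell_id = cells, cluster = 1L,
    identity = rep(rep(c("neuroblast", "otic_epithelial"), c(1, 9)), 7),
    stringsAsFactors = FALSE)), class = "identity_result")
  res <- neuroblast_fraction_test(ident, meta)
  expect_true(all(res$fractions$fraction == 0.1))
  expect_equal(res$test$t, 0)
  expect_equal(res$test$p, 1)
})

test_that("batch silhouettes are null for clean data, positive for shifts", {
  st <- generate_study(generator_spec(rng_seed = 1))
  pre <- preprocess(st$ct)
  b <- assess_batch_effects(pre$expr, pre$expr$meta)
  expect_true(all(abs(b$mean_silhouette) < 0.1))
  expect_true(all(!b$batch_structure))

  # randomly permuted embryo labels carry no structure either
  meta_perm <- pre$expr$meta
  set.seed(99)
  meta_perm$embryo_id <- sample(meta_perm$embryo_id)
  bp <- assess_batch_effects(pre$expr, meta_perm, labels = "embryo_id")
  expect_lt(abs(bp$mean_silhouette), 0.1)

  # positive control: shift half the genes by 5 Log2Ex on one plate
  raw <- to_log2ex(apply_lod(st$ct, 23))
  hit <- raw$meta$plate_id == "P1"
  raw$values[hit, 1:96] <- raw$values[hit, 1:96] + 5
  shifted <- range_scale(median_normalize(raw))
  bs <- assess_batch_effects(shifted, shifted$meta, labels = "plate_id")
  expect_gt(bs$mean_silhouette, 0.2)
  expect_true(bs$batch_structure)

  # single-level labels are skipped with a warning
  meta1 <- pre$expr$meta
  meta1$plate_id <- "P1"
  expect_warning(b1 <- assess_batch_effects(pre$expr, meta1,
                                            labels = "plate_id"))
  expect_true(is.na(b1$mean_silhouette))
})
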