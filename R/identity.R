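#' Two-sided Welch (unequal-variance) t-test
#'
#' Thin wrapper around [stats::t.test()] that also handles the degenerate
#' constant-data case `t.test()` refuses: two essentially constant groups
#' with equal means give `t = 0, p = 1`; with different means, `p = 0`.
#'
#' @param x,y Numeric vectors (>= 2 values each for a proper test).
#' @return List with `t`, `df` (Welch-Satterthwaite) and `p`.
#' @export
welch_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    abort("welch_test needs at least 2 observations per group",
          "otoctant_test_error")
  eps <- 10 * .Machine$double.eps
  if (stats::var(x) < eps * max(1, mean(x)^2) &&
      stats::var(y) < eps * max(1, mean(y)^2)) {
    same <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(t = if (same) 0 else sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2,
                p = if (same) 1 else 0))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Principal component analysis of an expression matrix
#'
#' Centered (unscaled) PCA of the cells-by-genes values. For
#' reproducibility, each component's sign is fixed so that its
#' largest-magnitude gene loading is positive.
#'
#' @param x An `expression_matrix` (typically `state = "scaled"`).
#' @param n_components Number of components to return.
#' @return List with `scores` (cells x components), `explained_variance`
#'   (proportions, all components) and `loadings`.
#' @export
run_pca <- function(x, n_components = 2) {
  stopifnot(inherits(x, "expression_matrix"))
  if (nrow(x$values) < n_components)
    abort("fewer cells than requested components", "otoctant_dim_error")
  nonconst <- apply(x$values, 2, function(v) stats::var(v) > 0)
  if (sum(nonconst) < n_components)
    abort("fewer non-constant genes than requested components",
          "otoctant_dim_error")
  p <- stats::prcomp(x$values, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  flip <- vapply(k, function(j) {
    l <- p$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(p$x[, k, drop = FALSE], 2, flip, "*")
  loadings <- sweep(p$rotation[, k, drop = FALSE], 2, flip, "*")
  list(scores = scores,
       explained_variance = p$sdev^2 / sum(p$sdev^2),
       loadings = loadings)
}

#' Cluster cells by k-means and hierarchical clustering
#'
#' k-means (Euclidean, `n_restarts` random starts) and hierarchical
#' clustering (Euclidean distance, complete linkage, tree cut at `k`
#' groups) on the same matrix, with their agreement summarized as the
#' adjusted Rand index.
#'
#' @param x An `expression_matrix`.
#' @param k Number of clusters (>= 2).
#' @param seed RNG seed; required, k-means is stochastic.
#' @param n_restarts Random restarts for k-means.
#' @return List with `kmeans` (integer labels), `hclust` (integer labels),
#'   `agreement` (adjusted Rand index between the two) and `km` (the
#'   [stats::kmeans()] fit).
#' @export
cluster_cells <- function(x, k = 2, seed = NULL, n_restarts = 10) {
  stopifnot(inherits(x, "expression_matrix"))
  seed <- resolve_seed(seed)
  if (k < 2) abort("k must be >= 2", "otoctant_config_error")
  if (k > nrow(x$values))
    abort("k exceeds the number of cells", "otoctant_dim_error")
  set.seed(seed)
  km <- stats::kmeans(x$values, centers = k, nstart = n_restarts)
  hc <- stats::hclust(stats::dist(x$values), method = "complete")
  hcl <- stats::cutree(hc, k = k)
  kml <- stats::setNames(unname(km$cluster), rownames(x$values))
  hcl <- stats::setNames(unname(hcl), rownames(x$values))
  list(kmeans = kml, hclust = hcl,
       agreement = mclust::adjustedRandIndex(kml, hcl), km = km)
}

#' Label clusters as neuroblast vs otic-epithelial by marker score
#'
#' For each of the two clusters, the neuroblast score is the mean scaled
#' expression of the neuroblast markers minus the mean of the epithelial
#' markers; the higher-scoring cluster is labeled `neuroblast`, the other
#' `otic_epithelial`. Deterministic marker-based labeling replaces manual
#' inspection of the clusters.
#'
#' @param clusters Integer cluster labels (exactly 2 distinct values),
#'   named by cell id.
#' @param x The scaled `expression_matrix` the clusters came from.
#' @param neuro_markers,epi_markers Marker panels (defaults Neurod1/Tubb3 vs
#'   Oc90/Lfng).
#' @return List of class `identity_result`: `cells` (data frame `cell_id`,
#'   `cluster`, `identity`), `cluster_scores`.
#' @export
label_clusters <- function(clusters, x,
                           neuro_markers = c("Neurod1", "Tubb3"),
                           epi_markers = c("Oc90", "Lfng")) {
  stopifnot(inherits(x, "expression_matrix"))
  ids <- sort(unique(clusters))
  if (length(ids) != 2)
    abort("marker labeling expects exactly 2 clusters",
          "otoctant_labeling_error")
  miss <- setdiff(c(neuro_markers, epi_markers), colnames(x$values))
  if (length(miss))
    abort(paste0("marker gene(s) not in panel: ",
                 paste(miss, collapse = ", ")),
          "otoctant_config_error")
  score <- vapply(ids, function(cl) {
    rows <- which(clusters == cl)
    mean(x$values[rows, neuro_markers, drop = FALSE]) -
      mean(x$values[rows, epi_markers, drop = FALSE])
  }, numeric(1))
  if (score[1] == score[2])
    abort("marker scores tie between clusters; cannot assign identities",
          "otoctant_labeling_error")
  nb_cluster <- ids[which.max(score)]
  cells <- data.frame(cell_id = names(clusters),
                      cluster = unname(clusters),
                      identity = ifelse(clusters == nb_cluster,
                                        "neuroblast", "otic_epithelial"),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(cells = cells,
                 cluster_scores = stats::setNames(score, ids)),
            class = "identity_result")
}

#' Per-embryo neuroblast fractions and genotype contrast
#'
#' Computes the fraction of neuroblast-labeled cells in each embryo and
#' compares the two genotypes' embryo-level fractions with a two-sided
#' Welch (unequal-variance) t-test. The embryo, not the cell, is the unit
#' of replication.
#'
#' @param identity An `identity_result` from [label_clusters()].
#' @param meta Per-cell annotation data frame (`cell_id`, `embryo_id`,
#'   `genotype`) covering all labeled cells.
#' @return List with `fractions` (data frame `embryo_id`, `genotype`, `n`,
#'   `n_neuroblast`, `fraction`) and `test` (`t`, `df`, `p`,
#'   `mean_wildtype`, `mean_mutant`).
#' @export
neuroblast_fraction_test <- function(identity, meta) {
  stopifnot(inherits(identity, "identity_result"))
  d <- merge(identity$cells, meta[, c("cell_id", "embryo_id", "genotype")],
             by = "cell_id")
  if (nrow(d) < nrow(identity$cells))
    abort("meta does not cover all labeled cells", "otoctant_linkage_error")
  agg <- do.call(rbind, lapply(split(d, d$embryo_id), function(g) {
    data.frame(embryo_id = g$embryo_id[1], genotype = g$genotype[1],
               n = nrow(g), n_neuroblast = sum(g$identity == "neuroblast"),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg$fraction <- agg$n_neuroblast / agg$n
  for (geno in c("wildtype", "mutant"))
    if (sum(agg$genotype == geno) < 2)
      abort(sprintf("need >= 2 embryos per genotype for the t-test; '%s' has %d",
                    geno, sum(agg$genotype == geno)),
            "otoctant_test_error")
  wt <- agg$fraction[agg$genotype == "wildtype"]
  mt <- agg$fraction[agg$genotype == "mutant"]
  res <- welch_test(mt, wt)
  res$mean_wildtype <- mean(wt)
  res$mean_mutant <- mean(mt)
  list(fractions = agg, test = res)
}

#' Silhouette-based batch-effect assessment
#'
#' Mean silhouette coefficient of each batch label (embryo, plate) in PC
#' space. Values near 0 indicate no batch structure; the claim "no
#' differences among cells by embryo or plate" corresponds to
#' `|mean silhouette| < threshold`.
#'
#' By default the average-neighbor silhouette variant is used: `b(i)` is the
#' mean distance to all cells outside `i`'s label, so the score is centered
#' at 0 when labels are exchangeable. The classical definition (`b(i)` =
#' mean distance to the nearest other label) is available via
#' `neighbor = "nearest"`, but is biased negative for many mutually
#' overlapping labels and should not be read against a symmetric threshold.
#'
#' @param x An `expression_matrix`.
#' @param meta Per-cell annotations aligned with `x` (matched by cell id).
#' @param labels Metadata columns to assess.
#' @param n_components PCs used for the distance computation.
#' @param threshold Absolute silhouette below which a label is reported as
#'   showing no batch structure.
#' @param neighbor `"average"` (default) or `"nearest"` (classical
#'   [cluster::silhouette()]).
#' @return Data frame: `label`, `n_levels`, `mean_silhouette`,
#'   `batch_structure` (logical; `NA` for skipped single-level labels).
#' @export
assess_batch_effects <- function(x, meta,
                                 labels = c("embryo_id", "plate_id"),
                                 n_components = 3, threshold = 0.1,
                                 neighbor = c("average", "nearest")) {
  stopifnot(inherits(x, "expression_matrix"))
  neighbor <- match.arg(neighbor)
  meta <- meta[match(rownames(x$values), meta$cell_id), , drop = FALSE]
  pcs <- run_pca(x, n_components = n_components)$scores
  d <- stats::dist(pcs)
  dm <- as.matrix(d)
  out <- lapply(labels, function(lab) {
    lv <- factor(meta[[lab]])
    if (nlevels(lv) < 2) {
      warning(sprintf("label '%s' has a single level; skipped", lab))
      return(data.frame(label = lab, n_levels = nlevels(lv),
                        mean_silhouette = NA_real_,
                        batch_structure = NA, stringsAsFactors = FALSE))
    }
    s <- if (neighbor == "nearest") {
      mean(cluster::silhouette(as.integer(lv), d)[, "sil_width"])
    } else {
      same <- outer(lv, lv, "==")
      other <- !same
      diag(same) <- FALSE                # exclude self from a(i)
      a <- rowSums(dm * same) / pmax(rowSums(same), 1)
      b <- rowSums(dm * other) / pmax(rowSums(other), 1)
      mean((b - a) / pmax(a, b))
    }
    data.frame(label = lab, n_levels = nlevels(lv), mean_silhouette = s,
               batch_structure = abs(s) >= threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify cells end to end
#'
#' PCA, clustering (k-means k = 2 by default), marker-based labeling and the
#' per-embryo genotype contrast, in one call.
#'
#' @param expr A scaled `expression_matrix`.
#' @param config A [pipeline_config()].
#' @param seed Seed for k-means (falls back to `config$rng_seed`).
#' @return List with `identity` (an `identity_result`), `clusters`, `pca`
#'   and `fraction_test`.
#' @export
classify_cells <- function(expr, config = pipeline_config(), seed = NULL) {
  seed <- resolve_seed(seed, config)
  cl <- cluster_cells(expr, k = config$kmeans_k, seed = seed,
                      n_restarts = config$n_kmeans_restarts)
  identity <- label_clusters(cl$kmeans, expr,
                             neuro_markers = config$neuro_markers,
                             epi_markers = config$epi_markers)
  pca <- run_pca(expr, n_components = 2)
  ft <- neuroblast_fraction_test(identity, expr$meta)
  list(identity = identity, clusters = cl, pca = pca, fraction_test = ft)
}
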