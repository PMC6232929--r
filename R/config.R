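#' Pipeline configuration
#'
#' Collects every tunable of the analysis in one validated object. The
#' defaults reproduce the published analysis settings: limit-of-detection
#' Ct of 23 cycles, Gapdh/Actb as housekeeping genes, 3-standard-deviation
#' QC fences, a two-cluster identity split, and significance at 0.05.
#'
#' @param lod_ct Limit-of-detection Ct (cycles); measurements at or beyond it
#'   are treated as undetected.
#' @param housekeeping_genes Constitutively expressed genes used for per-cell
#'   QC.
#' @param qc_sd_multiplier Width of the QC fences in standard deviations of
#'   the housekeeping statistic.
#' @param neuro_markers,epi_markers Marker panels used to label the two
#'   clusters as neuroblast vs otic-epithelial.
#' @param octant_model An [octant_model()] with the three axis panels.
#' @param kmeans_k Number of k-means clusters for the identity split.
#' @param n_kmeans_restarts Random restarts for k-means.
#' @param rng_seed Default seed for stochastic stages; stages refuse to run
#'   with `rng_seed = NULL` and no explicit seed.
#' @param alpha Significance level for all tests.
#' @param scaling_unit `"per_gene_global"` (default; keeps downstream
#'   cell-level tests calibrated) or `"per_gene_per_embryo"` (removes
#'   embryo-specific dynamic range but couples cells of an embryo through
#'   shared min-max denominators; best reserved for exploratory use).
#' @param min_cells_per_group Minimum expressing cells per group for a
#'   level test.
#' @param median_detected_only If `TRUE`, the cell median used in
#'   normalization is taken over detected genes only (default: all genes,
#'   zeros included).
#' @param floor_normalized If `TRUE` (default), detected values pushed below
#'   zero by the normalization shift are floored at 0.
#' @param p_adjust Multiple-testing correction method passed to
#'   [stats::p.adjust()] for the differential table (default "none").
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(lod_ct = 23,
                            housekeeping_genes = c("Gapdh", "Actb"),
                            qc_sd_multiplier = 3,
                            neuro_markers = c("Neurod1", "Tubb3"),
                            epi_markers = c("Oc90", "Lfng"),
                            octant_model = otoctant::octant_model(),
                            kmeans_k = 2,
                            n_kmeans_restarts = 10,
                            rng_seed = NULL,
                            alpha = 0.05,
                            scaling_unit = c("per_gene_global",
                                             "per_gene_per_embryo"),
                            min_cells_per_group = 3,
                            median_detected_only = FALSE,
                            floor_normalized = TRUE,
                            p_adjust = "none") {
  scaling_unit <- match.arg(scaling_unit)
  if (!is.numeric(lod_ct) || lod_ct <= 0)
    abort("lod_ct must be > 0", "otoctant_config_error")
  if (!is.numeric(qc_sd_multiplier) || qc_sd_multiplier <= 0)
    abort("qc_sd_multiplier must be > 0", "otoctant_config_error")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    abort("alpha must lie in (0, 1)", "otoctant_config_error")
  if (!is.numeric(kmeans_k) || kmeans_k < 2)
    abort("kmeans_k must be >= 2", "otoctant_config_error")
  if (!inherits(octant_model, "octant_model"))
    abort("octant_model must be built with octant_model()",
          "otoctant_config_error")
  structure(list(lod_ct = lod_ct,
                 housekeeping_genes = housekeeping_genes,
                 qc_sd_multiplier = qc_sd_multiplier,
                 neuro_markers = neuro_markers,
                 epi_markers = epi_markers,
                 octant_model = octant_model,
                 kmeans_k = as.integer(kmeans_k),
                 n_kmeans_restarts = as.integer(n_kmeans_restarts),
                 rng_seed = rng_seed,
                 alpha = alpha,
                 scaling_unit = scaling_unit,
                 min_cells_per_group = as.integer(min_cells_per_group),
                 median_detected_only = isTRUE(median_detected_only),
                 floor_normalized = isTRUE(floor_normalized),
                 p_adjust = p_adjust),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; absent keys keep their
#' defaults. Axis panels may be given under `octant_model:` as
#' `dv/ap/ml: {positive: [...], negative: [...]}`.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    abort(paste0("config file not found: ", path), "otoctant_io_error")
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$octant_model)) {
    om <- raw$octant_model
    defaults <- octant_model()
    for (ax in c("dv", "ap", "ml"))
      if (is.null(om[[ax]])) om[[ax]] <- defaults$axes[[ax]]
    raw$octant_model <- octant_model(dv = om$dv, ap = om$ap, ml = om$ml)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
          "otoctant_config_error")
  do.call(pipeline_config, raw)
}

#' Resolve the seed for a stochastic stage
#' @keywords internal
resolve_seed <- function(seed, config = NULL) {
  if (is.null(seed) && !is.null(config)) seed <- config$rng_seed
  if (is.null(seed))
    abort("this stage is stochastic and requires a seed (explicit or via config rng_seed)",
          "otoctant_config_error")
  as.integer(seed)
}
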