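#' Apply the limit-of-detection rule
#'
#' Measurements with `Ct >= lod_ct` (including no-amplification sentinels)
#' are below assay sensitivity and are treated as negative, i.e. undetected.
#' The rule is recorded as a logical detection mask alongside the Ct matrix;
#' Ct values themselves are left untouched.
#'
#' @param x A [ct_matrix()].
#' @param lod_ct Limit-of-detection Ct (cycles), default 23.
#' @return `x` with elements `detection` (logical matrix, `TRUE` = detected)
#'   and `lod_ct` added.
#' @export
apply_lod <- function(x, lod_ct = 23) {
  stopifnot(inherits(x, "ct_matrix"))
  if (lod_ct <= 0) abort("lod_ct must be > 0", "otoctant_config_error")
  x$detection <- is.finite(x$ct) & x$ct < lod_ct
  x$lod_ct <- lod_ct
  x
}

# housekeeping statistic: per-cell mean Log2Ex over the housekeeping genes,
# undetected entries counted as 0
hk_statistic <- function(x, housekeeping, lod_ct) {
  miss <- setdiff(housekeeping, colnames(x$ct))
  if (length(miss))
    abort(paste0("housekeeping gene(s) not in panel: ",
                 paste(miss, collapse = ", ")),
          "otoctant_config_error")
  sub <- x$ct[, housekeeping, drop = FALSE]
  log2ex <- ifelse(is.finite(sub) & sub < lod_ct, lod_ct - sub, 0)
  rowMeans(log2ex)
}

#' Housekeeping-based cell quality control
#'
#' Cells whose mean housekeeping (default Gapdh/Actb) Log2Ex lies more than
#' `k` standard deviations below the population mean are flagged
#' `compromised` (degraded cell); more than `k` SDs above, `multiplet`
#' (multiple cells captured together). Flagged cells are removed from the
#' returned matrix; the report retains a flag for every input cell.
#'
#' @param x A [ct_matrix()].
#' @param housekeeping Housekeeping gene ids; must be in the panel.
#' @param k Fence width in SDs (default 3).
#' @param lod_ct Limit-of-detection Ct used for the Log2Ex statistic.
#' @return List with `filtered` (a `ct_matrix` of passing cells), `report`
#'   (data frame: `cell_id`, `hk_log2ex`, `flag`), `mu`, `sigma`, and
#'   `n_excluded`.
#' @export
qc_cells <- function(x, housekeeping = c("Gapdh", "Actb"), k = 3,
                     lod_ct = 23) {
  stopifnot(inherits(x, "ct_matrix"))
  if (nrow(x$ct) < 2)
    abort("QC needs at least 2 cells", "otoctant_format_error")
  if (k <= 0) abort("qc_sd_multiplier must be > 0", "otoctant_config_error")
  stat <- hk_statistic(x, housekeeping, lod_ct)
  mu <- mean(stat)
  sigma <- stats::sd(stat)
  flag <- rep("ok", length(stat))
  if (sigma > 0) {
    flag[stat < mu - k * sigma] <- "compromised"
    flag[stat > mu + k * sigma] <- "multiplet"
  }
  report <- data.frame(cell_id = rownames(x$ct), hk_log2ex = stat,
                       flag = flag, stringsAsFactors = FALSE,
                       row.names = NULL)
  keep <- rownames(x$ct)[flag == "ok"]
  list(filtered = subset_cells(x, keep), report = report,
       mu = mu, sigma = sigma, n_excluded = sum(flag != "ok"))
}

new_expression_matrix <- function(values, detection, state, meta,
                                  lod_ct, shifts = NULL) {
  structure(list(values = values, detection = detection, state = state,
                 meta = meta, lod_ct = lod_ct, shifts = shifts),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix [%s]: %d cells x %d genes; detected %.1f%%\n",
              x$state, nrow(x$values), ncol(x$values),
              100 * mean(x$detection)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Transform censored Ct values to Log2Ex
#'
#' Log2Ex is expression on a log2 scale relative to the limit of detection:
#' `Log2Ex = lod_ct - Ct` for detected entries, 0 for undetected ones (one
#' Ct cycle = one doubling of template). Requires [apply_lod()] to have run.
#'
#' @param x A `ct_matrix` carrying a detection mask.
#' @return An `expression_matrix` with `state = "log2ex_raw"`: elements
#'   `values`, `detection`, `meta`, `lod_ct`.
#' @export
to_log2ex <- function(x) {
  stopifnot(inherits(x, "ct_matrix"))
  if (is.null(x$detection))
    abort("run apply_lod() before to_log2ex()", "otoctant_state_error")
  values <- matrix(0, nrow(x$ct), ncol(x$ct), dimnames = dimnames(x$ct))
  values[x$detection] <- x$lod_ct - x$ct[x$detection]
  new_expression_matrix(values, x$detection, "log2ex_raw", x$meta, x$lod_ct)
}

#' Median normalization of Log2Ex values
#'
#' For every cell the median Log2Ex over all genes is computed (zeros from
#' undetected genes included, by default); the difference between this
#' cell-characteristic median and the mean of all cell medians is subtracted
#' from the cell's detected values. Undetected entries stay exactly 0 —
#' shifting a censored zero would fabricate expression — and detected values
#' pushed below 0 by the shift are floored at 0 (configurable).
#'
#' @param x An `expression_matrix` with `state = "log2ex_raw"`.
#' @param detected_only Use only detected genes for the cell median.
#' @param floor Floor shifted detected values at 0 (default `TRUE`).
#' @return An `expression_matrix` with `state = "normalized"` and per-cell
#'   `shifts` (their mean is 0 by construction).
#' @export
median_normalize <- function(x, detected_only = FALSE, floor = TRUE) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$state != "log2ex_raw")
    abort("median_normalize expects state 'log2ex_raw'",
          "otoctant_state_error")
  if (nrow(x$values) < 1)
    abort("need at least one cell", "otoctant_format_error")
  m <- if (detected_only) {
    vapply(seq_len(nrow(x$values)), function(i) {
      v <- x$values[i, x$detection[i, ]]
      if (length(v)) stats::median(v) else 0
    }, numeric(1))
  } else {
    apply(x$values, 1, stats::median)
  }
  shifts <- m - mean(m)
  values <- x$values - matrix(shifts, nrow(x$values), ncol(x$values))
  values[!x$detection] <- 0
  if (floor) values[values < 0 & x$detection] <- 0
  out <- new_expression_matrix(values, x$detection, "normalized", x$meta,
                               x$lod_ct, shifts = shifts)
  names(out$shifts) <- rownames(x$values)
  out
}

#' Range (min-max) standardization to [0, 1]
#'
#' Within each scaling unit, `x' = (x - min(x)) / (max(x) - min(x))`,
#' which maps the unit to [0, 1] while preserving rank order and relative
#' separation. The default unit is one gene over all cells. The alternative,
#' one gene within one embryo, removes embryo-specific dynamic range, but
#' every cell of an embryo then shares that embryo's random min-max
#' denominator, which makes pooled cell-level tests downstream
#' anticonservative; it is offered for exploratory use. Constant units (e.g.
#' a gene never detected in a unit) map to 0.
#'
#' @param x An `expression_matrix` with `state = "normalized"`.
#' @param unit `"per_gene_global"` (default) or `"per_gene_per_embryo"`.
#' @return An `expression_matrix` with `state = "scaled"`, values in [0, 1].
#' @export
range_scale <- function(x, unit = c("per_gene_global",
                                    "per_gene_per_embryo")) {
  stopifnot(inherits(x, "expression_matrix"))
  unit <- match.arg(unit)
  if (x$state != "normalized")
    abort("range_scale expects state 'normalized'", "otoctant_state_error")
  values <- x$values
  scale_block <- function(rows) {
    block <- values[rows, , drop = FALSE]
    lo <- apply(block, 2, min)
    hi <- apply(block, 2, max)
    rng <- hi - lo
    rng[rng == 0] <- 1                   # constant unit -> (x - lo)/1 = 0
    values[rows, ] <<- sweep(sweep(block, 2, lo), 2, rng, "/")
  }
  if (unit == "per_gene_per_embryo") {
    for (e in unique(x$meta$embryo_id))
      scale_block(which(x$meta$embryo_id == e))
  } else {
    scale_block(seq_len(nrow(values)))
  }
  values[!x$detection] <- 0
  new_expression_matrix(values, x$detection, "scaled", x$meta, x$lod_ct,
                        shifts = x$shifts)
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper: [apply_lod()] -> [qc_cells()] -> [to_log2ex()] ->
#' [median_normalize()] -> [range_scale()], driven by a [pipeline_config()].
#'
#' @param x A raw [ct_matrix()].
#' @param config A `pipeline_config`.
#' @return List with `expr` (scaled `expression_matrix`), `qc` (the
#'   [qc_cells()] result) and `normalized` (the pre-scaling matrix).
#' @export
preprocess <- function(x, config = pipeline_config()) {
  qc <- qc_cells(x, housekeeping = config$housekeeping_genes,
                 k = config$qc_sd_multiplier, lod_ct = config$lod_ct)
  censored <- apply_lod(qc$filtered, config$lod_ct)
  raw <- to_log2ex(censored)
  normalized <- median_normalize(raw,
                                 detected_only = config$median_detected_only,
                                 floor = config$floor_normalized)
  expr <- range_scale(normalized, unit = config$scaling_unit)
  list(expr = expr, qc = qc, normalized = normalized)
}
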