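#' @keywords internal
abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "otoctant_error")))
}

#' Ct value used internally for "no amplification"
#'
#' Reactions that never cross the detection threshold carry no cycle number.
#' They are stored as `Inf` so that any limit-of-detection rule
#' (`Ct >= lod_ct`) classifies them as undetected without a special case.
#'
#' @export
CT_SENTINEL <- Inf

#' Construct a single-cell qPCR Ct matrix
#'
#' Bundles a cells-by-genes matrix of raw cycle-threshold (Ct) values with
#' per-cell annotations. Ct is the PCR cycle at which amplification crosses
#' the detection threshold; lower Ct means more template. Reactions with no
#' amplification are encoded as [CT_SENTINEL] (`Inf`).
#'
#' @param ct Numeric matrix, one row per cell, one column per gene (amplicon).
#'   Row and column names are taken as cell and gene identifiers.
#' @param meta Data frame with columns `cell_id`, `embryo_id`, `plate_id`,
#'   `genotype`; `genotype` must only contain `"wildtype"` and `"mutant"`.
#'   One row per cell of `ct`, matched by `cell_id` (order may differ).
#' @return An object of class `ct_matrix`: a list with elements `ct`
#'   (matrix, meta-aligned rows), `meta` (data frame) and, after
#'   [apply_lod()], `detection` (logical matrix) and `lod_ct`.
#' @seealso [read_ct_matrix()], [apply_lod()], [qc_cells()]
#' @export
ct_matrix <- function(ct, meta) {
  if (!is.matrix(ct) || !is.numeric(ct))
    abort("`ct` must be a numeric matrix", "otoctant_format_error")
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    abort("`ct` must have cell ids as rownames and gene ids as colnames",
          "otoctant_format_error")
  if (anyDuplicated(rownames(ct)))
    abort("duplicate cell ids in Ct matrix", "otoctant_format_error")
  if (anyDuplicated(colnames(ct)))
    abort("duplicate gene ids in Ct matrix", "otoctant_format_error")
  required <- c("cell_id", "embryo_id", "plate_id", "genotype")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    abort(paste0("meta is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          "otoctant_format_error")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  meta$cell_id <- as.character(meta$cell_id)
  if (anyDuplicated(meta$cell_id))
    abort("duplicate cell ids in meta table", "otoctant_format_error")
  unmatched <- setdiff(rownames(ct), meta$cell_id)
  if (length(unmatched))
    abort(paste0("cell(s) in Ct matrix but not in meta: ",
                 paste(unmatched, collapse = ", ")),
          "otoctant_linkage_error")
  extra <- setdiff(meta$cell_id, rownames(ct))
  if (length(extra))
    abort(paste0("cell(s) in meta but not in Ct matrix: ",
                 paste(extra, collapse = ", ")),
          "otoctant_linkage_error")
  bad_geno <- setdiff(unique(as.character(meta$genotype)),
                      c("wildtype", "mutant"))
  if (length(bad_geno))
    abort(paste0("genotype must be 'wildtype' or 'mutant'; found: ",
                 paste(bad_geno, collapse = ", ")),
          "otoctant_format_error")
  if (anyNA(ct))
    abort("Ct matrix contains NA; encode no-amplification as Inf",
          "otoctant_format_error")
  if (any(ct[is.finite(ct)] < 0))
    abort("negative Ct values are not valid cycle numbers",
          "otoctant_format_error")
  meta <- meta[match(rownames(ct), meta$cell_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(ct = ct, meta = meta), class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("ct_matrix: %d cells x %d genes\n", nrow(x$ct), ncol(x$ct)))
  tab <- table(x$meta$genotype)
  cat("genotypes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat(sprintf("no-amplification entries: %d (%.1f%%)\n",
              sum(is.infinite(x$ct)),
              100 * mean(is.infinite(x$ct))))
  if (!is.null(x$detection))
    cat(sprintf("LOD applied at Ct = %g; detected: %.1f%%\n",
                x$lod_ct, 100 * mean(x$detection)))
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) dim(x$ct)

#' Subset a Ct matrix to a set of cells
#'
#' @param x A `ct_matrix`.
#' @param cells Character vector of cell ids (or logical/integer index).
#' @return A `ct_matrix` restricted to `cells`, detection mask included if
#'   present.
#' @export
subset_cells <- function(x, cells) {
  stopifnot(inherits(x, "ct_matrix"))
  if (is.character(cells)) {
    miss <- setdiff(cells, rownames(x$ct))
    if (length(miss))
      abort(paste0("unknown cell id(s): ", paste(miss, collapse = ", ")),
            "otoctant_linkage_error")
  }
  out <- x
  out$ct <- x$ct[cells, , drop = FALSE]
  out$meta <- x$meta[match(rownames(out$ct), x$meta$cell_id), , drop = FALSE]
  rownames(out$meta) <- NULL
  if (!is.null(x$detection))
    out$detection <- x$detection[cells, , drop = FALSE]
  out
}
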