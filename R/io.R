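#' Read a raw Ct matrix and its annotation table
#'
#' The matrix file is delimited text with a header row of gene ids and a
#' leading cell-id column; the annotation file is keyed by `cell_id` and
#' carries `embryo_id`, `plate_id`, `genotype`. No-amplification entries
#' (empty field, `NA`, or the platform's `999` convention) are mapped to the
#' internal `Inf` sentinel. The delimiter is inferred from the file
#' extension (`.csv` = comma, otherwise tab) unless given.
#'
#' @param path Ct matrix file.
#' @param meta_path Annotation file.
#' @param sep Field delimiter; `NULL` to infer from the extension.
#' @return A validated [ct_matrix()].
#' @export
read_ct_matrix <- function(path, meta_path, sep = NULL) {
  for (f in c(path, meta_path))
    if (!file.exists(f))
      abort(paste0("file not found: ", f), "otoctant_io_error")
  infer <- function(f) if (grepl("\\.csv$", f, ignore.case = TRUE)) "," else "\t"
  m <- utils::read.table(path, header = TRUE,
                         sep = if (is.null(sep)) infer(path) else sep,
                         check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(m) < 2)
    abort("Ct matrix needs a cell-id column plus at least one gene",
          "otoctant_format_error")
  cell_ids <- m[[1]]
  raw <- as.matrix(m[, -1, drop = FALSE])
  sentinel <- raw %in% c("", "NA", "999", "999.0") | is.na(raw)
  ct <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  if (any(is.na(ct) & !sentinel)) {
    bad <- which(is.na(ct) & !sentinel, arr.ind = TRUE)[1, ]
    abort(sprintf("non-numeric Ct value '%s' at cell '%s', gene '%s'",
                  raw[bad[1], bad[2]], cell_ids[bad[1]],
                  colnames(m)[-1][bad[2]]),
          "otoctant_parse_error")
  }
  ct[sentinel] <- CT_SENTINEL
  dimnames(ct) <- list(cell_ids, colnames(m)[-1])
  meta <- utils::read.table(meta_path, header = TRUE,
                            sep = if (is.null(sep)) infer(meta_path) else sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
  ct_matrix(ct, meta)
}

#' Write a Ct matrix and its annotation table
#'
#' Inverse of [read_ct_matrix()]: tab-delimited, '.' decimal separator,
#' no-amplification sentinel written as `NA`.
#'
#' @param x A `ct_matrix`.
#' @param path,meta_path Output files.
#' @return Invisibly, the two paths.
#' @export
write_ct_matrix <- function(x, path, meta_path) {
  stopifnot(inherits(x, "ct_matrix"))
  ct <- x$ct
  ct[is.infinite(ct)] <- NA
  df <- data.frame(cell_id = rownames(ct),
                   signif(ct, 6), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, meta_path))
}

#' Write an expression matrix with its state and detection mask
#'
#' Values go to `path` (TSV, 6 significant digits, first header line a
#' `# state:` comment), the detection mask to `mask_path` as 0/1.
#'
#' @param x An `expression_matrix`.
#' @param path,mask_path Output files.
#' @return Invisibly, the paths.
#' @export
write_expression_matrix <- function(x, path, mask_path) {
  stopifnot(inherits(x, "expression_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# state: %s lod_ct: %g", x$state, x$lod_ct), con)
  df <- data.frame(cell_id = rownames(x$values), signif(x$values, 6),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  mask <- data.frame(cell_id = rownames(x$values), x$detection * 1L,
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(mask, mask_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, mask_path))
}

#' Read an expression matrix written by [write_expression_matrix()]
#'
#' @param path,mask_path Files written by [write_expression_matrix()].
#' @param meta Per-cell annotation data frame covering the matrix cells.
#' @return An `expression_matrix`.
#' @export
read_expression_matrix <- function(path, mask_path, meta) {
  header <- readLines(path, n = 1)
  if (!grepl("^# state: ", header))
    abort("missing '# state:' header line", "otoctant_format_error")
  state <- sub("^# state: (\\S+).*", "\\1", header)
  lod_ct <- as.numeric(sub(".*lod_ct: ", "", header))
  m <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                         check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(m[, -1, drop = FALSE])
  rownames(values) <- m[[1]]
  mk <- utils::read.table(mask_path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  detection <- as.matrix(mk[, -1, drop = FALSE]) == 1
  rownames(detection) <- mk[[1]]
  meta <- meta[match(rownames(values), meta$cell_id), , drop = FALSE]
  if (anyNA(meta$cell_id))
    abort("meta does not cover all matrix cells", "otoctant_linkage_error")
  rownames(meta) <- NULL
  new_expression_matrix(values, detection[rownames(values), , drop = FALSE],
                        state, meta, lod_ct)
}

#' Write result tables plus run metadata
#'
#' Writes each table as TSV with stable column order ('.' decimal
#' separator, 6 significant digits for numeric columns) and a
#' `run_metadata.yaml` recording the package version, seed, configuration
#' and a timestamp (the only line that differs between identical reruns).
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @param config Optional `pipeline_config` to record.
#' @param seed Optional seed to record.
#' @return Invisibly, the written file paths.
#' @export
write_results <- function(tables, out_dir, config = NULL, seed = NULL) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    abort(paste0("cannot create output directory: ", out_dir),
          "otoctant_io_error")
  if (file.access(out_dir, 2) != 0)
    abort(paste0("output directory not writable: ", out_dir),
          "otoctant_io_error")
  paths <- character(0)
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], signif, digits = 6)
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tab, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  meta <- list(package = "otoctant",
               version = as.character(utils::packageVersion("otoctant")),
               seed = seed,
               config = serialize_config(config))
  mp <- file.path(out_dir, "run_metadata.yaml")
  yaml::write_yaml(meta, mp)
  cat(sprintf("timestamp: %s\n", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
      file = mp, append = TRUE)
  invisible(c(paths, mp))
}

serialize_config <- function(config) {
  if (is.null(config)) return(NULL)
  out <- unclass(config)
  if (!is.null(out$octant_model))
    out$octant_model <- out$octant_model$axes
  out
}
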