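#' Per-cell axis scores from marker panels
#'
#' For each of the three otocyst axes, a cell's score is the mean scaled
#' expression of the axis's positive-pole panel minus the mean of its
#' negative-pole panel; with scaled values in [0, 1] every score lies in
#' [-1, 1]. The sign of the score places the cell on one side of the axis
#' midplane. Only otic-epithelial cells belong on the otocyst sphere, so
#' callers restrict `cells` to that identity.
#'
#' @param x A scaled `expression_matrix`.
#' @param cells Cell ids to score (typically the epithelial subset).
#' @param model An [octant_model()].
#' @return Numeric matrix, cells x 3 (`dv`, `ap`, `ml`), rownames = cell id.
#' @export
compute_axis_scores <- function(x, cells = rownames(x$values),
                                model = octant_model()) {
  stopifnot(inherits(x, "expression_matrix"),
            inherits(model, "octant_model"))
  miss <- setdiff(octant_model_genes(model), colnames(x$values))
  if (length(miss))
    abort(paste0("axis panel gene(s) not in matrix: ",
                 paste(miss, collapse = ", ")),
          "otoctant_config_error")
  v <- x$values[cells, , drop = FALSE]
  scores <- vapply(model$axes, function(ax) {
    rowMeans(v[, ax$positive, drop = FALSE]) -
      rowMeans(v[, ax$negative, drop = FALSE])
  }, numeric(length(cells)))
  scores <- matrix(scores, ncol = 3,
                   dimnames = list(cells, names(model$axes)))
  scores
}

#' Assign cells to otocyst octants from their axis scores
#'
#' An octant is the sign triple of the three axis scores, looked up in the
#' model's octant table. Exact-zero scores are tie-broken toward the
#' positive pole (the number of such ties is returned). For visualization,
#' each score vector is normalized to unit length to give a position on the
#' model sphere; all-zero score vectors are placed at the center, flagged,
#' and excluded from octant summaries downstream.
#'
#' @param scores Matrix from [compute_axis_scores()].
#' @param model An [octant_model()].
#' @return Data frame of class `octant_assignment`: `cell_id`, the three
#'   scores, `octant`, `octant_name`, unit-sphere coordinates
#'   (`sphere_dv/ap/ml`), `center_flag`; attribute `n_zero_ties`.
#' @export
assign_octants <- function(scores, model = octant_model()) {
  stopifnot(is.matrix(scores), ncol(scores) == 3)
  n_zero_ties <- sum(scores == 0)
  sgn <- ifelse(scores >= 0, 1L, -1L)     # zero -> positive pole
  key <- paste(sgn[, 1], sgn[, 2], sgn[, 3])
  tab <- model$octants
  idx <- match(key, paste(tab$dorsal, tab$anterior, tab$lateral))
  norms <- sqrt(rowSums(scores^2))
  center <- norms == 0
  unit <- scores / ifelse(norms == 0, 1, norms)
  out <- data.frame(cell_id = rownames(scores),
                    score_dv = scores[, 1], score_ap = scores[, 2],
                    score_ml = scores[, 3],
                    octant = ifelse(center, NA_integer_, tab$octant[idx]),
                    octant_name = ifelse(center, NA_character_,
                                         tab$name[idx]),
                    sphere_dv = unit[, 1], sphere_ap = unit[, 2],
                    sphere_ml = unit[, 3],
                    center_flag = center,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_zero_ties") <- n_zero_ties
  class(out) <- c("octant_assignment", "data.frame")
  out
}

#' Reconstruct the in-silico otocyst
#'
#' Scores the epithelial cells on the three axes and assigns octants.
#'
#' @param expr A scaled `expression_matrix`.
#' @param identity An `identity_result`; only cells labeled
#'   `otic_epithelial` are placed on the sphere.
#' @param model An [octant_model()].
#' @return An `octant_assignment` for the epithelial cells.
#' @export
reconstruct_otocyst <- function(expr, identity, model = octant_model()) {
  epi <- identity$cells$cell_id[identity$cells$identity == "otic_epithelial"]
  if (!length(epi))
    abort("no otic-epithelial cells to reconstruct", "otoctant_dim_error")
  assign_octants(compute_axis_scores(expr, epi, model), model)
}

#' Per-octant expression summary
#'
#' For every gene x octant x genotype: number of cells, percent expressing
#' (share of cells whose measurement was detected, i.e. above the limit of
#' detection), and a five-number summary (min, Q1, median, Q3, max) of the
#' scaled expression levels over the expressing cells only. Center-flagged
#' cells are excluded.
#'
#' @param expr A scaled `expression_matrix` (detection mask is used for
#'   "expressing").
#' @param assignment An `octant_assignment`.
#' @param genes Genes to summarize (default: all).
#' @return Data frame: `gene`, `octant`, `genotype`, `n`, `n_expressing`,
#'   `pct_expressing`, `min`, `q1`, `median`, `q3`, `max` (level columns
#'   `NA` where no cell expresses).
#' @export
octant_summary <- function(expr, assignment,
                           genes = colnames(expr$values)) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(assignment, "octant_assignment"))
  a <- assignment[!assignment$center_flag, , drop = FALSE]
  meta <- expr$meta[match(a$cell_id, expr$meta$cell_id), , drop = FALSE]
  grid <- expand.grid(gene = genes, octant = 1:8,
                      genotype = c("wildtype", "mutant"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid$gene[i]
    cells <- a$cell_id[a$octant == grid$octant[i] &
                         meta$genotype == grid$genotype[i]]
    det <- expr$detection[cells, g]
    vals <- expr$values[cells, g][det]
    fn <- if (length(vals)) stats::fivenum(vals) else rep(NA_real_, 5)
    data.frame(gene = g, octant = grid$octant[i],
               genotype = grid$genotype[i],
               n = length(cells), n_expressing = sum(det),
               pct_expressing = if (length(cells))
                 100 * mean(det) else NA_real_,
               min = fn[1], q1 = fn[2], median = fn[3], q3 = fn[4],
               max = fn[5], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Octant-resolved differential expression between genotypes
#'
#' For every gene x octant, two contrasts between mutant and wild-type
#' epithelial cells: (i) `p_level`, a two-sided Welch t-test on the scaled
#' expression levels of expressing cells, computed only when both genotypes
#' have at least `min_cells` expressing cells in the octant; (ii)
#' `p_fraction`, Fisher's exact test on the 2x2 detected/undetected counts,
#' computed when both genotypes have at least `min_cells` cells in the
#' octant. The two p-values are reported side by side, not combined; a row
#' is significant when any computed p-value falls below `alpha`. No
#' multiple-testing correction is applied by default (`p_adjust = "none"`).
#'
#' @param expr A scaled `expression_matrix`.
#' @param assignment An `octant_assignment` over the epithelial cells.
#' @param genes Genes to test (default: all).
#' @param alpha Significance level.
#' @param min_cells Minimum group size (default 3).
#' @param p_adjust Method for [stats::p.adjust()], applied per p-value
#'   column across all rows.
#' @return Data frame of class `differential_result`: `gene`, `octant`,
#'   `n_wt`, `n_mut`, `n_expr_wt`, `n_expr_mut`, `pct_wt`, `pct_mut`,
#'   `delta_pct`, `mean_wt`, `mean_mut`, `delta_level`, `t_level`,
#'   `p_level`, `p_fraction`, `significant`.
#' @export
differential_octant_expression <- function(expr, assignment,
                                           genes = colnames(expr$values),
                                           alpha = 0.05, min_cells = 3,
                                           p_adjust = "none") {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(assignment, "octant_assignment"))
  a <- assignment[!assignment$center_flag, , drop = FALSE]
  geno <- expr$meta$genotype[match(a$cell_id, expr$meta$cell_id)]
  rows <- vector("list", length(genes) * 8L)
  k <- 0L
  for (oct in 1:8) {
    wt_cells <- a$cell_id[a$octant == oct & geno == "wildtype"]
    mt_cells <- a$cell_id[a$octant == oct & geno == "mutant"]
    det_wt <- expr$detection[wt_cells, , drop = FALSE]
    det_mt <- expr$detection[mt_cells, , drop = FALSE]
    val_wt <- expr$values[wt_cells, , drop = FALSE]
    val_mt <- expr$values[mt_cells, , drop = FALSE]
    for (g in genes) {
      k <- k + 1L
      dw <- det_wt[, g]; dm <- det_mt[, g]
      vw <- val_wt[dw, g]; vm <- val_mt[dm, g]
      pct_wt <- if (length(dw)) 100 * mean(dw) else NA_real_
      pct_mut <- if (length(dm)) 100 * mean(dm) else NA_real_
      p_level <- t_level <- NA_real_
      if (length(vw) >= min_cells && length(vm) >= min_cells) {
        wt_res <- welch_test(vm, vw)
        p_level <- wt_res$p
        t_level <- wt_res$t
      }
      p_fraction <- NA_real_
      if (length(dw) >= min_cells && length(dm) >= min_cells) {
        tab <- matrix(c(sum(dw), sum(!dw), sum(dm), sum(!dm)), 2)
        p_fraction <- stats::fisher.test(tab)$p.value
      }
      rows[[k]] <- data.frame(
        gene = g, octant = oct,
        n_wt = length(dw), n_mut = length(dm),
        n_expr_wt = sum(dw), n_expr_mut = sum(dm),
        pct_wt = pct_wt, pct_mut = pct_mut,
        delta_pct = pct_mut - pct_wt,
        mean_wt = if (length(vw)) mean(vw) else NA_real_,
        mean_mut = if (length(vm)) mean(vm) else NA_real_,
        delta_level = (if (length(vm)) mean(vm) else NA_real_) -
          (if (length(vw)) mean(vw) else NA_real_),
        t_level = t_level, p_level = p_level, p_fraction = p_fraction,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (p_adjust != "none") {
    out$p_level <- stats::p.adjust(out$p_level, method = p_adjust)
    out$p_fraction <- stats::p.adjust(out$p_fraction, method = p_adjust)
  }
  out$significant <- (!is.na(out$p_level) & out$p_level < alpha) |
    (!is.na(out$p_fraction) & out$p_fraction < alpha)
  rownames(out) <- NULL
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Notch-panel summary of the differential table
#'
#' Restricts the differential table to the Notch-pathway panel (defaults
#' Hey1, Hey2, Lfng, Dll1, Notch3, Hes1), tabulates the per-octant direction
#' of change (mutant minus wild type, using the level difference where
#' available, otherwise the percent-expressing difference) and significance,
#' and aggregates ventral octants (5-8) against dorsal octants (1-4).
#'
#' @param diff A `differential_result`.
#' @param panel Panel gene ids.
#' @return List with `table` (per gene x octant: delta, direction,
#'   significant), `aggregate` (per compartment: n up/down, n significant,
#'   mean deltas) and `missing` (panel genes absent from the table).
#' @export
notch_panel_report <- function(diff, panel = NOTCH_PANEL) {
  stopifnot(inherits(diff, "differential_result"))
  missing <- setdiff(panel, unique(diff$gene))
  present <- intersect(panel, unique(diff$gene))
  if (!length(present)) {
    warning("no Notch panel genes present in the differential table")
    return(list(table = diff[0, ], aggregate = NULL, missing = missing))
  }
  tab <- diff[diff$gene %in% present, , drop = FALSE]
  tab$delta <- ifelse(is.na(tab$delta_level), tab$delta_pct,
                      tab$delta_level)
  tab$direction <- ifelse(is.na(tab$delta), NA_character_,
                          ifelse(tab$delta > 0, "up",
                                 ifelse(tab$delta < 0, "down", "flat")))
  tab$compartment <- ifelse(tab$octant <= 4, "dorsal", "ventral")
  agg <- do.call(rbind, lapply(split(tab, tab$compartment), function(g) {
    data.frame(compartment = g$compartment[1],
               n_tests = sum(!is.na(g$delta)),
               n_up = sum(g$direction == "up", na.rm = TRUE),
               n_down = sum(g$direction == "down", na.rm = TRUE),
               n_significant = sum(g$significant, na.rm = TRUE),
               mean_delta_level = mean(g$delta_level, na.rm = TRUE),
               mean_delta_pct = mean(g$delta_pct, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  keep <- c("gene", "octant", "compartment", "delta_pct", "delta_level",
            "delta", "direction", "p_level", "p_fraction", "significant")
  list(table = tab[, keep], aggregate = agg, missing = missing)
}
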