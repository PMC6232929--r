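# tiny hand-checkable fixtures used across test files

toy_meta <- function(cell_ids, genotype = "wildtype", embryo = "WT1",
                     plate = "P1") {
  data.frame(cell_id = cell_ids,
             embryo_id = rep_len(embryo, length(cell_ids)),
             plate_id = rep_len(plate, length(cell_ids)),
             genotype = rep_len(genotype, length(cell_ids)),
             stringsAsFactors = FALSE)
}

toy_ct <- function(values, cell_ids = sprintf("c%d", seq_len(nrow(values))),
                   gene_ids = sprintf("g%d", seq_len(ncol(values))),
                   meta = toy_meta(cell_ids)) {
  dimnames(values) <- list(cell_ids, gene_ids)
  ct_matrix(values, meta)
}

# expression_matrix straight from a values matrix (detected = value > 0)
toy_expr <- function(values, state = "scaled", meta = NULL, lod_ct = 23) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("c%d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("g%d", seq_len(ncol(values)))
  if (is.null(meta)) meta <- toy_meta(rownames(values))
  otoctant:::new_expression_matrix(values, values > 0, state, meta, lod_ct)
}

# closed-form Welch t-test, independent of stats::t.test
welch_oracle <- function(x, y) {
  v1 <- sum((x - mean(x))^2) / (length(x) - 1)
  v2 <- sum((y - mean(y))^2) / (length(y) - 1)
  se2 <- v1 / length(x) + v2 / length(y)
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / length(x))^2 / (length(x) - 1) +
                   (v2 / length(y))^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum of P(k) over all tables with P(k) <= P(observed) * (1 + 1e-7)
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  ks <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(ks, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# zero-noise generator settings: expression a deterministic function of truth
noise_free_spec <- function(seed = 1, ...) {
  generator_spec(rng_seed = seed, noise_sd = 0, embryo_baseline_sd = 0,
                 dropout_enabled = FALSE,
                 qc_spike = c(compromised = 0, multiplet = 0), ...)
}
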