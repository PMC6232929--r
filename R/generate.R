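#' Default 192-amplicon gene panel for the synthetic study
#'
#' A stand-in for the curated developmental panel assayed in the study:
#' housekeeping genes (Gapdh, Actb), neuroblast markers (Neurod1, Tubb3,
#' Neurog1), dorsoventral markers (Oc90, Bmp4, Wnt2b vs Lfng), Notch-pathway
#' genes (Hey1, Hey2, Hes1, Dll1, Notch3), anteroposterior and mediolateral
#' patterning genes matching [octant_model()] defaults, 15 + 15 synthetic
#' identity-programme amplicons (`NbProg*`, `EpiProg*`; a curated panel
#' carries many genes that covary with cell identity, not just the named
#' markers) and synthetic filler amplicons (`Filler*`) up to `n_genes`.
#'
#' @param n_genes Total panel size (default 192).
#' @return Character vector of gene ids.
#' @export
default_gene_panel <- function(n_genes = 192) {
  named <- c("Gapdh", "Actb",
             "Neurod1", "Tubb3", "Neurog1",
             "Oc90", "Bmp4", "Wnt2b", "Lfng",
             "Hey1", "Hey2", "Hes1", "Dll1", "Notch3",
             "Fgf3", "Fgf10", "Tbx1", "Otx2",
             "Dlx5", "Gata3", "Gbx2", "Pax8",
             sprintf("NbProg%02d", 1:15),
             sprintf("EpiProg%02d", 1:15))
  if (n_genes < length(named))
    abort(sprintf("n_genes must be >= %d to hold the named markers",
                  length(named)),
          "otoctant_spec_error")
  c(named, sprintf("Filler%03d", seq_len(n_genes - length(named))))
}

#' Specification of the synthetic single-cell qPCR study
#'
#' Defines the generative model used to emulate the study design: 3 wild-type
#' and 4 heterozygous-mutant embryos, ~68 cells per embryo (~476 total,
#' matching the ~479 collected in the emulated design), a 192-amplicon
#' panel, genotype-specific neuroblast fractions (15.3% wild type, 44.2%
#' mutant), uniform positions on the unit sphere for epithelial cells,
#' compartmental marker expression, logistic limit-of-detection dropout and
#' spiked QC-failing cells.
#'
#' Latent expression is drawn in Log2Ex space (log2 expression units above
#' the limit of detection) and converted to Ct as `lod_ct - Log2Ex`, so the
#' preprocessing transform inverts the generator exactly; axis markers are
#' expressed compartmentally (high within their pole's half of the otocyst,
#' low outside), following the compartment-boundary model of otocyst
#' patterning.
#'
#' @param n_embryos Named counts, e.g. `c(wildtype = 3, mutant = 4)`.
#' @param cells_per_embryo Cells collected per embryo.
#' @param neuroblast_fraction Named per-genotype ground-truth neuroblast
#'   fractions.
#' @param n_genes Panel size; must accommodate all named markers.
#' @param gene_panel Gene ids (default [default_gene_panel()]).
#' @param lod_ct Limit-of-detection Ct used for the Ct conversion.
#' @param noise_sd SD of Gaussian noise added to latent Log2Ex (log2 units;
#'   roughly one PCR cycle of technical plus biological noise).
#' @param hk_mean Housekeeping latent mean (Log2Ex).
#' @param neuro_marker_mean Latent mean of neuroblast markers in neuroblasts.
#' @param marker_high,marker_low Latent mean of a compartment/programme gene
#'   inside vs outside its compartment (epithelial cells).
#' @param off_level Latent mean of lineage-inappropriate markers.
#' @param filler_mean Latent mean of filler amplicons.
#' @param dropout_midpoint,dropout_steepness Logistic detection model:
#'   `P(detected) = plogis(steepness * (Log2Ex - midpoint))`; low expression
#'   drops out more.
#' @param dropout_enabled Set `FALSE` for a fully detected matrix.
#' @param embryo_logit_sd SD of the per-embryo jitter applied to
#'   `qlogis(neuroblast_fraction)`.
#' @param embryo_baseline_sd SD of a per-embryo additive shift applied to all
#'   latent values (embryo-specific dynamic range).
#' @param qc_spike Named counts `c(compromised = 2, multiplet = 2)` of cells
#'   whose housekeeping signal is displaced below/above the population.
#' @param spike_sd_multiplier Displacement of spiked cells in SDs of the
#'   housekeeping QC statistic (>= 5 so a 3-SD fence must catch them).
#' @param notch_upshift Log2Ex added to the Notch panel (Hey1, Hey2, Lfng,
#'   Dll1, Notch3, Hes1) in mutant ventral epithelial cells; 0 disables the
#'   genotype effect.
#' @param n_plates Assay plates over which cells are distributed.
#' @param rng_seed Seed; generation refuses to run without one.
#' @return A list of class `generator_spec`.
#' @seealso [generate_study()], [generate_null_study()]
#' @export
generator_spec <- function(n_embryos = c(wildtype = 3, mutant = 4),
                           cells_per_embryo = 68,
                           neuroblast_fraction = c(wildtype = 0.153,
                                                   mutant = 0.442),
                           n_genes = 192,
                           gene_panel = default_gene_panel(n_genes),
                           lod_ct = 23,
                           noise_sd = 1.0,
                           hk_mean = 15,
                           neuro_marker_mean = 8,
                           marker_high = 7,
                           marker_low = 1,
                           off_level = 0.5,
                           filler_mean = 3,
                           dropout_midpoint = 2.0,
                           dropout_steepness = 1.5,
                           dropout_enabled = TRUE,
                           embryo_logit_sd = 0.2,
                           embryo_baseline_sd = 0.3,
                           qc_spike = c(compromised = 2, multiplet = 2),
                           spike_sd_multiplier = 5,
                           notch_upshift = 0,
                           n_plates = 5,
                           rng_seed = NULL) {
  if (cells_per_embryo < 1)
    abort("cells_per_embryo must be >= 1", "otoctant_spec_error")
  if (any(neuroblast_fraction < 0 | neuroblast_fraction > 1))
    abort("neuroblast fractions must lie in [0, 1]", "otoctant_spec_error")
  if (noise_sd < 0 || embryo_logit_sd < 0 || embryo_baseline_sd < 0)
    abort("SDs must be >= 0", "otoctant_spec_error")
  if (!all(c("wildtype", "mutant") %in% names(n_embryos)) ||
      !all(c("wildtype", "mutant") %in% names(neuroblast_fraction)))
    abort("n_embryos and neuroblast_fraction need 'wildtype' and 'mutant' entries",
          "otoctant_spec_error")
  required <- c("Gapdh", "Actb", "Neurod1", "Tubb3", "Neurog1",
                octant_model_genes(octant_model()),
                "Hey1", "Hey2", "Hes1", "Dll1", "Notch3")
  miss <- setdiff(required, gene_panel)
  if (length(miss))
    abort(paste0("gene_panel is missing marker gene(s): ",
                 paste(miss, collapse = ", ")),
          "otoctant_spec_error")
  structure(as.list(environment()), class = "generator_spec")
}

NOTCH_PANEL <- c("Hey1", "Hey2", "Lfng", "Dll1", "Notch3", "Hes1")

# latent-mean matrix given identities and coordinates; the deterministic part
# of the generative model, shared by generate_study and zero-noise tests
latent_means <- function(spec, nb, coords, genotype) {
  genes <- spec$gene_panel
  n <- length(nb)
  M <- matrix(spec$filler_mean, n, length(genes),
              dimnames = list(NULL, genes))
  M[, c("Gapdh", "Actb")] <- spec$hk_mean
  neuro <- c("Neurod1", "Tubb3", "Neurog1")
  nbprog <- grep("^NbProg", genes, value = TRUE)
  epiprog <- grep("^EpiProg", genes, value = TRUE)
  M[, neuro] <- ifelse(nb, spec$neuro_marker_mean, spec$off_level)
  M[, nbprog] <- ifelse(nb, spec$marker_high, spec$off_level)
  M[, epiprog] <- ifelse(nb, spec$off_level, spec$marker_high)
  model <- octant_model()
  axis_coord <- list(dv = coords[, "dorsal"], ap = coords[, "anterior"],
                     ml = coords[, "lateral"])
  for (ax in names(model$axes)) {
    for (pole in c("positive", "negative")) {
      s <- if (pole == "positive") +1 else -1
      for (g in model$axes[[ax]][[pole]]) {
        v <- ifelse(s * axis_coord[[ax]] > 0, spec$marker_high,
                    spec$marker_low)
        M[, g] <- ifelse(nb, spec$off_level, v)
      }
    }
  }
  # Notch effectors: ventral-compartment genes, like Lfng
  for (g in setdiff(NOTCH_PANEL, octant_model_genes(model))) {
    v <- ifelse(coords[, "dorsal"] < 0, spec$marker_high, spec$marker_low)
    M[, g] <- ifelse(nb, spec$off_level, v)
  }
  if (spec$notch_upshift != 0) {
    hit <- !nb & genotype == "mutant" & coords[, "dorsal"] < 0
    M[hit, NOTCH_PANEL] <- M[hit, NOTCH_PANEL] + spec$notch_upshift
  }
  M
}

#' Generate a synthetic single-cell qPCR study
#'
#' Draws a full study according to a [generator_spec()]: per-embryo identity
#' fractions (logit-jittered around the genotype value), per-cell identities,
#' uniform sphere positions for epithelial cells, latent Log2Ex values,
#' logistic dropout, conversion to Ct, and spiked QC failures whose
#' housekeeping statistic is displaced by `spike_sd_multiplier` SDs.
#'
#' @param spec A `generator_spec`; `rng_seed` must be set.
#' @return List with `ct` (a [ct_matrix()]) and `truth`, a per-cell data
#'   frame of ground-truth identity, QC status, sphere coordinate and octant
#'   (epithelial cells only; neuroblasts carry `NA` coordinates/octant).
#' @examples
#' study <- generate_study(generator_spec(rng_seed = 1))
#' table(study$truth$genotype, study$truth$identity)
#' @export
generate_study <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  seed <- resolve_seed(spec$rng_seed)
  set.seed(seed)

  genotype_of_embryo <- rep(c("wildtype", "mutant"),
                            times = c(spec$n_embryos[["wildtype"]],
                                      spec$n_embryos[["mutant"]]))
  embryo_ids <- c(sprintf("WT%d", seq_len(spec$n_embryos[["wildtype"]])),
                  sprintf("MT%d", seq_len(spec$n_embryos[["mutant"]])))
  n_emb <- length(embryo_ids)
  n <- n_emb * spec$cells_per_embryo
  embryo <- rep(embryo_ids, each = spec$cells_per_embryo)
  genotype <- rep(genotype_of_embryo, each = spec$cells_per_embryo)
  cell_id <- sprintf("cell%04d", seq_len(n))
  plate <- sprintf("P%d", sample.int(spec$n_plates, n, replace = TRUE))

  # per-embryo neuroblast fraction: logit jitter around the genotype value
  frac_emb <- stats::plogis(
    stats::qlogis(spec$neuroblast_fraction[genotype_of_embryo]) +
      stats::rnorm(n_emb, 0, spec$embryo_logit_sd))
  nb <- stats::rbinom(n, 1, frac_emb[match(embryo, embryo_ids)]) == 1

  # uniform points on the unit sphere for epithelial cells
  u <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  coords <- cbind(dorsal = u,
                  anterior = sqrt(1 - u^2) * cos(phi),
                  lateral = sqrt(1 - u^2) * sin(phi))

  M <- latent_means(spec, nb, coords, genotype)
  b <- stats::rnorm(n_emb, 0, spec$embryo_baseline_sd)
  latent <- M + b[match(embryo, embryo_ids)] +
    stats::rnorm(length(M), 0, spec$noise_sd)

  detected <- if (spec$dropout_enabled) {
    matrix(stats::runif(length(latent)) <
             stats::plogis(spec$dropout_steepness *
                             (latent - spec$dropout_midpoint)),
           nrow(latent), ncol(latent))
  } else {
    matrix(TRUE, nrow(latent), ncol(latent))
  }

  ct <- matrix(CT_SENTINEL, n, length(spec$gene_panel),
               dimnames = list(cell_id, spec$gene_panel))
  ct[detected] <- pmin(pmax(spec$lod_ct - latent[detected], 1e-6),
                       spec$lod_ct)

  # spiked QC failures: housekeeping statistic displaced by exactly
  # +/- spike_sd_multiplier SDs of the statistic's sampling distribution
  qc_status <- rep("ok", n)
  hk <- c("Gapdh", "Actb")
  n_spike <- sum(spec$qc_spike)
  if (n_spike > 0) {
    if (n_spike > n)
      abort("more QC spikes than cells", "otoctant_spec_error")
    idx <- sample.int(n, n_spike)
    sigma_stat <- sqrt(spec$embryo_baseline_sd^2 +
                         spec$noise_sd^2 / length(hk))
    shift <- spec$spike_sd_multiplier * sigma_stat
    comp <- idx[seq_len(spec$qc_spike[["compromised"]])]
    mult <- setdiff(idx, comp)
    ct[comp, hk] <- pmin(pmax(spec$lod_ct - (spec$hk_mean - shift), 1e-6),
                         spec$lod_ct)
    ct[mult, hk] <- pmin(pmax(spec$lod_ct - (spec$hk_mean + shift), 1e-6),
                         spec$lod_ct)
    qc_status[comp] <- "compromised"
    qc_status[mult] <- "multiplet"
  }

  octants <- octant_model()$octants
  key <- paste(sign(coords[, "dorsal"]), sign(coords[, "anterior"]),
               sign(coords[, "lateral"]))
  true_oct <- octants$octant[match(key, paste(octants$dorsal,
                                              octants$anterior,
                                              octants$lateral))]
  truth <- data.frame(cell_id = cell_id,
                      embryo_id = embryo,
                      plate_id = plate,
                      genotype = genotype,
                      identity = ifelse(nb, "neuroblast", "otic_epithelial"),
                      qc_status = qc_status,
                      dorsal = ifelse(nb, NA_real_, coords[, "dorsal"]),
                      anterior = ifelse(nb, NA_real_, coords[, "anterior"]),
                      lateral = ifelse(nb, NA_real_, coords[, "lateral"]),
                      octant = ifelse(nb, NA_integer_, true_oct),
                      stringsAsFactors = FALSE)
  meta <- truth[, c("cell_id", "embryo_id", "plate_id", "genotype")]
  list(ct = ct_matrix(ct, meta), truth = truth, spec = spec)
}

#' Generate a null study with no genotype effect
#'
#' Identical to [generate_study()] except that both genotypes share every
#' distributional parameter: the neuroblast fraction of both genotypes is set
#' to the mean of the spec's two values and the Notch upshift is disabled.
#' Genotype labels are then independent of all expression ground truth, which
#' makes this the calibration harness for the type-I error of the
#' differential tests.
#'
#' @inheritParams generate_study
#' @return As [generate_study()].
#' @export
generate_null_study <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  p <- mean(spec$neuroblast_fraction[c("wildtype", "mutant")])
  spec$neuroblast_fraction <- c(wildtype = p, mutant = p)
  spec$notch_upshift <- 0
  generate_study(spec)
}
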