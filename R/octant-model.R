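#' The eight-octant model of the E10.5 otocyst
#'
#' The otocyst is a near-spherical epithelium compartmentalized along three
#' embryologic axes: dorsoventral (DV), anteroposterior (AP) and mediolateral
#' (ML). Crossing the three axis midplanes yields eight octants, each
#' associated with specific derivatives (e.g. the endolymphatic duct and
#' semicircular canals dorsally, the cochlea ventrally). Each axis carries a
#' marker panel for its positive pole and one for its negative pole; the sign
#' convention is positive = dorsal, anterior, lateral, so that octant 1 (ADL)
#' is the all-positive reference octant.
#'
#' Dorsal markers default to Oc90, Bmp4 and Wnt2b with Lfng marking the
#' ventral pole. The AP and ML panels default to otocyst patterning genes
#' (anterior Fgf3/Fgf10, posterior Tbx1/Otx2, medial Gbx2/Pax8, lateral
#' Dlx5/Gata3) and should be replaced whenever a panel better matched to the
#' assay at hand is available.
#'
#' @param dv,ap,ml Per-axis lists with character elements `positive` and
#'   `negative`, the marker panels of the two poles.
#' @return An object of class `octant_model`: list with `axes` (the three
#'   panels) and `octants`, a data frame mapping octant ids 1-8 and names
#'   (ADL, PDL, PDM, ADM, AVM, PVM, PVL, AVL) to sign triples over
#'   (dorsal, anterior, lateral).
#' @examples
#' m <- octant_model()
#' m$octants
#' @export
octant_model <- function(dv = list(positive = c("Oc90", "Bmp4", "Wnt2b"),
                                   negative = "Lfng"),
                         ap = list(positive = c("Fgf3", "Fgf10"),
                                   negative = c("Tbx1", "Otx2")),
                         ml = list(positive = c("Dlx5", "Gata3"),
                                   negative = c("Gbx2", "Pax8"))) {
  axes <- list(dv = dv, ap = ap, ml = ml)
  for (ax in names(axes)) {
    for (pole in c("positive", "negative")) {
      panel <- axes[[ax]][[pole]]
      if (is.null(panel) || !length(panel) || !is.character(panel))
        abort(sprintf("axis '%s' needs a non-empty %s-pole marker panel",
                      ax, pole),
              "otoctant_config_error")
    }
  }
  octants <- data.frame(
    octant  = 1:8,
    name    = c("ADL", "PDL", "PDM", "ADM", "AVM", "PVM", "PVL", "AVL"),
    dorsal  = c(+1, +1, +1, +1, -1, -1, -1, -1),
    anterior = c(+1, -1, -1, +1, +1, -1, -1, +1),
    lateral = c(+1, +1, -1, -1, -1, -1, +1, +1),
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(paste(octants$dorsal, octants$anterior,
                                 octants$lateral)))
  structure(list(axes = axes, octants = octants), class = "octant_model")
}

#' @export
print.octant_model <- function(x, ...) {
  cat("octant_model (sign convention: + = dorsal, anterior, lateral)\n")
  for (ax in names(x$axes))
    cat(sprintf("  %s: [+] %s  vs  [-] %s\n", ax,
                paste(x$axes[[ax]]$positive, collapse = ","),
                paste(x$axes[[ax]]$negative, collapse = ",")))
  print(x$octants)
  invisible(x)
}

#' All marker genes referenced by an octant model
#' @param model An `octant_model`.
#' @return Character vector of the distinct panel genes.
#' @export
octant_model_genes <- function(model) {
  unique(unlist(lapply(model$axes, function(a) c(a$positive, a$negative)),
                use.names = FALSE))
}
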