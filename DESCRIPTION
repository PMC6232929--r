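Package: otoctant
Title: Octant-Resolved Single-Cell qPCR Analysis of the Embryonic Otocyst
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for single-cell multiplex qPCR profiling of the
    E10.5 mouse otocyst: limit-of-detection censoring, housekeeping-based cell
    quality control, Log2Ex transformation, median normalization and per-embryo
    range scaling, marker-based classification of delaminating neuroblasts versus
    otic epithelial cells, in-silico assignment of epithelial cells to the eight
    anatomical octants of the otocyst via signed marker-panel axis scores, and
    octant-resolved differential expression between genotypes (percent-expressing
    and expression-level contrasts), including a Notch-pathway panel report. A
    synthetic-data generator reproduces the statistical structure of the study
    design (genotype-specific identity composition, spatial compartments,
    dropout, spiked QC failures) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    mclust,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
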