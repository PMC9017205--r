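Package: hmtiquant
Title: Cell-Type-Specific Segmentation, Spatial Spillover Correction and
    Single-Cell Quantification for Highly Multiplexed Tissue Imaging
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated quantification of highly multiplexed tissue imaging
    (HMTI) data from per-channel grayscale TIFF tiles to a flow-cytometry
    compatible per-cell feature matrix. Implements tile stitching, watershed
    nuclei segmentation with separate epithelial and non-epithelial passes and
    compartment-specific particle filters, surface-marker pre-processing
    (outlier and minimum filters), quadrant-based spatial spillover correction
    (SSC) that deletes per-cell marker signals concentrated on one side of a
    cell, per-cell mean-intensity measurement, quality-control exclusions,
    signal-to-noise evaluation, FCS 3.1 export, and replotting of gated cell
    populations onto tissue coordinates. A synthetic tissue-image generator
    with full ground truth (crypt-like epithelium, membrane-stained immune
    cells, mutually exclusive marker pairs, spillover artefacts, antibody
    aggregate speckles) makes the whole pipeline testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    grDevices,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
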