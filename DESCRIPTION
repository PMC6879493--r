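Package: spaRQ
Title: Spatial Phenotyping of Serial-Section Immunohistochemistry
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Registration and spatial quantification of DAB-stained serial
    tissue sections. Registers moving sections to a reference image with an
    iterative similarity transform driven by mutual information (Spa-R),
    separates hematoxylin and DAB by optical-density colour deconvolution,
    thresholds per-stain channels into binary masks, and quantifies per-ROI
    DAB-positive areas, their pairwise overlap, signalling-signature
    subclasses and pseudo-coloured overlap landscapes (Spa-Q). Includes a
    synthetic serial-section slide generator with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tiff,
    png,
    jpeg,
    jsonlite,
    yaml,
    zip,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
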