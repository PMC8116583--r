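Package: fundusIOD
Title: Imaging Indicators of the Optic Disc from Fundus Photograph Radiomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs quantitative imaging indicators of the optic disc
    (IODs) for macular and peripapillary choroidal thickness from colour
    fundus photographs. Builds peripapillary regions of interest from
    manual disc, atrophy and fovea annotations with axial-length
    magnification correction, extracts a radiomic feature pool (first-order,
    co-occurrence, run-length, size-zone, neighbourhood-tone-difference and
    dependence texture families plus 2D shape descriptors) over CIELAB
    channels, orders features along a LASSO regularisation path, chooses the
    feature count by an adjusted-R-squared stopping rule on a held-out set,
    and fits linear indicator models. A synthetic-cohort generator renders
    disc-centred fundus images with known planted geometry and
    choroidal-thickness signal so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    glmnet,
    jsonlite,
    png,
    pracma,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
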