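Package: CaMPARIquant
Title: Quantification of CaMPARI2 Photoconversion in Well-Plate Calcium Assays
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying calcium-dependent green-to-red
    photoconversion of the CaMPARI2 indicator in 96-well high-content
    screens, including parabolic-flight campaigns. Provides a forward
    model of Ca2+-dependent photoconversion kinetics (Hill occupancy and
    saturating hazard), a ground-truthed synthetic two-channel image
    generator emulating transfected chondrocyte monolayers, a
    reimplementation of the high-content mask (top-hat background
    removal, thresholding, hole fill, area filtering and green/red
    object classification), per-well photoconversion metrics, assay
    statistics (one-way ANOVA with Tukey post-test, Z'-factor,
    saturation-curve fitting with bootstrap confidence bands), and the
    flight illumination schedule with its LED thermal budget.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tiff,
    yaml,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: CellBasedAssays, Software, Visualization
RoxygenNote: 7.3.3
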