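Package: epitube
Title: Mechanics and Morphometrics of Biased Epithelial Tube Elongation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and quantification toolkit for studying biased
    elongation of embryonic epithelial tubes (lung, kidney). Provides a
    proliferating two-dimensional vertex model of the apical epithelium under
    longitudinally biased boundary forces, a continuum stretch-and-bend model
    of epithelial tube cross-section collapse under pressure, clamps or lumen
    drainage, closed-form and numerical wall-shear-stress estimators for
    laminar lumen flow, a skeleton-based branch morphometrics pipeline for 2D
    explant time series, and synthetic-data generators with exact ground truth
    for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Matrix,
    EBImage,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
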