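Package: sirsynergy
Title: Nonparametric Drug-Synergy Testing via Shape-Constrained Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tests for interaction between two drugs on a dose-response
    viability grid without parametric curve fitting. The observed surface is
    projected onto the cone of coordinatewise monotone surfaces (weighted 2D
    isotonic regression) and onto the nested monotone-additive subclass that
    encodes "no interaction"; their difference is the interaction surface.
    A global interaction energy is tested with a degrees-of-freedom-corrected
    Rademacher wild bootstrap, giving calibrated per-matrix p-values suitable
    for false-discovery-rate control in large combination screens. Also
    provides pointwise Bliss and HSA baseline surfaces, missing-well
    prediction from the fitted monotone surface, concordance statistics,
    and a synthetic-data simulator for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
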