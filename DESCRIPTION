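Package: cecbbb
Title: Blood-Brain Barrier Permeability Profiling from Capillary
    Electrochromatography and Potentiometric Titration Data
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for an integrative in vitro blood-brain barrier (BBB)
    permeability workflow built on open-tubular capillary
    electrochromatography (CEC) with liposome-coated capillaries. Converts
    migration times into the dimensionless retention factor k' and
    electroosmotic-flow mobility summaries; derives aqueous pKa by
    Yasuda-Shedlovsky extrapolation, log P from dual-phase (octanol) pKa
    shifts, and log D at arbitrary pH under a neutral-species partition
    model, including forward Bjerrum curve simulation; fits and applies a
    three-predictor ordinary-least-squares model of in vivo log BB on k',
    log D7.4 and pKa with prediction intervals and parity diagnostics; and
    classifies whole electropherogram traces into three CNS-permeability
    classes with a probability-blended ensemble of a dynamic-time-warping
    k-nearest-neighbour classifier and a Bag-of-SFA-Symbols in Vector Space
    (BOSSVS) model, evaluated by nested stratified cross-validation. Seeded
    synthetic-data generators for traces, cosolvent titrations and
    regression tables make every stage testable end to end. A curated
    57-compound reference table ships with the package.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    pROC,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
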