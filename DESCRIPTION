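Package: vascbci
Title: Signal Strength and Implant Geometry Analysis for Endovascular
    Stent-Electrode Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing motor signal strength recorded by
    stent-mounted electrode arrays implanted in the superior sagittal
    sinus, and for relating it to user-specific anatomical and clinical
    factors. Implements the high-gamma (100-200 Hz) burst-density
    sensitivity index (d-prime) over cued move/rest blocks, stent
    centerline approximation with stent-to-cortex distances, rostro-caudal
    region-of-interest overlap, sinus width and cortical thickness
    quantification, a coronal-slice activation center-of-gravity targeting
    analysis, and a small-cohort predictor screen (exact Spearman
    correlations, Lasso feature selection, nonparametric rank tests).
    Includes a synthetic-cohort generator with planted ground truth so
    every stage of the pipeline is verifiable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    signal,
    stats,
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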