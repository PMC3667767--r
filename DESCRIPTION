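Package: sphingodyn
Title: Dynamic Enzyme-Activity Inference for Yeast Sphingolipid Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for General Mass Action (GMA) power-law ODE models of
    metabolic pathways, with a focus on the heat-stress response of
    sphingolipid metabolism in Saccharomyces cerevisiae. Provides a
    simulable GMA model container with piecewise-constant enzyme
    activities, a bundled steady-state core model of the sphingolipid
    pathway plus an SBML importer for power-law models, smoothing-spline
    preparation of sparse fold-change time courses, piecewise Monte-Carlo
    inference of time-varying enzyme-activity profiles with SSE/AICc
    ensemble selection, identifiability summaries with 95% envelopes,
    validation computations (mean-activity refit, complex-sphingolipid
    flatness, clamped-enzyme negative controls, cumulative production,
    Q10 estimation), and a synthetic-data generator that serves as a
    ground-truth recovery oracle for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    Matrix,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
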