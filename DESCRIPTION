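Package: chaoswolf
Title: Chaos-Integrated Grey Wolf Optimization for Wrapper Feature
    Selection in Text Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the new improved Grey Wolf Optimizer (NI-GWO) with
    dimension-learning-based hunting and its four chaos-integrated variants
    (CNI-GWO1-4), which replace pseudo-random draws at population
    initialization or in the hunting coefficients with Circle, Logistic, or
    Iterative chaotic map sequences. The optimizer drives wrapper feature
    selection over binary document-term matrices with a multi-objective
    fitness combining k-nearest-neighbour accuracy and feature-subset size,
    targeted at depression detection in short social-media texts. Includes
    a text preprocessing pipeline, confusion-matrix metrics (accuracy,
    precision, sensitivity, F-measure, MCC), a repeated-run experiment
    protocol with box-plot quartiles and the tie-corrected Friedman rank
    test, and a synthetic planted-feature corpus generator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
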