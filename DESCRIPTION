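Package: fluorfit
Title: Parameter Estimation for Single-Molecule Protein Fluorosequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates the per-cycle error rates of single-molecule protein
    fluorosequencing experiments from reads of per-peptide fluorescence
    intensity time series. Implements two estimators: a modified Baum-Welch
    expectation-maximization over a merged-state hidden Markov model with a
    factored transition matrix, in which the M-step computes weighted maximum
    likelihood estimates of the tied physical parameters (Edman failure,
    peptide detachment, dye loss, missing-fluorophore "dud" rates, and initial
    and cyclic N-terminal blocking) together with an iterative censoring
    correction for invisible all-dud peptides; and a derivative-free fitter
    that minimizes the root-mean-square error between observed and simulated
    dye-track count histograms using a coordinate-trisection global search
    followed by coordinate-descent (Powell-style) refinement. Includes a Monte
    Carlo read simulator, percentile-bootstrap confidence intervals, intensity
    model fitting, contaminant read filtering, and tidy accessors for all
    results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
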