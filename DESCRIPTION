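Package: sucroselc
Title: Diagnostic Accuracy of Blood Sucrose Screening for Gastric Ulcers
    in Foals
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Statistical pipeline for evaluating blood sucrose concentration
    as a screening test for equine gastric ulcer syndrome in weanling foals.
    Provides frequentist receiver-operating-characteristic analysis with a
    foal-level cluster bootstrap that respects the repeated-measures design
    (AUC confidence intervals, paired AUC comparison, Youden-index cutoff
    selection, sensitivity/specificity against gastroscopy as gold standard,
    exact McNemar pre/post comparison, incidence rates, Cohen's kappa), and a
    Bayesian three-test two-population Hui-Walter latent class model with
    conditional dependence between the two sucrose measurements, fitted by an
    adaptive Metropolis-within-Gibbs sampler with Gelman-Rubin convergence
    diagnostics.  A synthetic cohort generator reproduces the statistical
    structure of the study design so the whole pipeline is testable without
    access to raw clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    pROC,
    rjags,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
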