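Package: pgebv
Title: Phenomics-Assisted Genomic Prediction in Biparental Maize Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for phenomics-assisted genomic
    prediction of grain yield in a biparental doubled-haploid maize population
    evaluated in multi-environment alpha-lattice trials with repeated canopy
    hyperspectral measurements. Provides a doubled-haploid genotype simulator
    with Haldane recombination and GBS-like noise, a sliding-window SNP
    quality-control and bin-map construction algorithm, per-environment mixed
    model BLUEs and broad-sense repeatability via REML, from-scratch
    implementations of partial least squares regression, random forest, ridge
    regression and BayesB, and within-environment two-fold plus
    leave-one-environment-out cross-validation with bootstrap standard errors
    of prediction accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    vcfR
Config/testthat/edition: 3
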