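Package: ovocond
Title: Eggshell Water-Vapor Conductance and Phylogenetic Comparative Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates eggshell water-vapor conductance (G_H2O) from egg
    mass-loss time series with regression-based quality control, quantifies
    eggshell pores (functional vs. occluded) from calibrated SEM-like
    grayscale images, and performs phylogenetic comparative inference of
    trait-elevation relationships: maximum-likelihood fitting of Brownian
    motion, Pagel's lambda, Ornstein-Uhlenbeck and early-burst trait-evolution
    models with AICc model selection, phylogenetic generalized least squares,
    simulation-based phylogenetic ANOVA, Levene-type variance comparison, and
    repeatability (intraclass correlation) with bootstrap confidence
    intervals. Includes synthetic-data generators (trees, traits with
    elevation effects, mass-loss series, SEM-like pore fields) with known
    ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    EBImage,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    nlme,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
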