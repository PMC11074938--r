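Package: mcaonet
Title: Consensus Neural-Network Ensembles and Frequentist Baselines for
    Small-Sample Preclinical Stroke Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for asking whether a small two-group preclinical study
    (the motivating design is a splenectomy versus sham cohort followed
    longitudinally after middle cerebral artery occlusion, MCAO) carries a
    group signal that per-timepoint frequentist tests cannot resolve.  The
    package generates synthetic cohorts with realistic longitudinal
    structure, fits per-cell parameter estimators (mean, SD, t-based 95%
    confidence intervals), simulates large artificial populations from those
    estimators, trains bootstrap ensembles of multilayer perceptrons with a
    consensus (majority) vote, runs an exhaustive variable-exclusion by
    day-exclusion ablation grid, and compares per-class prediction
    accuracies with Dunnett-adjusted many-to-one tests.  The frequentist
    baseline suite (Shapiro-Wilk gate, Welch and Student t tests, one-way
    and repeated-measures ANOVA with Greenhouse-Geisser correction,
    Kruskal-Wallis) is included for side-by-side reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    mvtnorm,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    jsonlite
Config/testthat/edition: 3
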