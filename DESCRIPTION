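Package: hybzone
Title: Hybrid Zone Genomics and Reciprocal-Transplant Selection Analysis
Version: 0.1.0
Authors@R:
    person("Hybzone", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing plant hybrid zones spanning sharp habitat
    ecotones. Implements supervised two-pool admixture-proportion estimation
    from biallelic SNP dosages, maximum-likelihood assignment of individuals
    to parental and early-generation hybrid categories (F1, F2, first
    backcrosses), distance-binned sigmoid (tanh) geographic cline fitting
    with bootstrap uncertainty, leaf-morphometric principal-component hybrid
    indices, reciprocal-transplant fitness analysis (composite fitness,
    selection coefficients with truncated bootstrap intervals, negative
    binomial GLM interaction tests), and backward-stepwise hierarchical
    log-linear analysis of cause-specific mortality via iterative
    proportional fitting. A seeded synthetic-data generator emulates the
    full sampling design so every stage can be exercised and validated
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    S4Vectors
Config/testthat/edition: 3
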