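Package: mcgreml
Title: Monte Carlo Single-Step Genomic REML for Variance Component Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Restricted maximum likelihood estimation of (co)variance components
    for single-step genomic BLUP (ssGBLUP) mixed models in which the traces of
    prediction-error-variance blocks are approximated by Hutchinson-type Monte
    Carlo simulation of breeding values under the exact ssGBLUP covariance
    structure, including an APY (algorithm for proven and young) variant.
    Provides pedigree relationship machinery (inbreeding, Henderson's rules,
    tabular A), VanRaden genomic relationships with polygenic blending and a
    J-factor base alignment, an implicit H-inverse operator, sparse mixed model
    equations with a preconditioned conjugate gradient solver, EM and
    average-information REML updates with structural-zero masks, an exact dense
    oracle for validation, and a synthetic data generator for multi-trait
    maternal-effects animal models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
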