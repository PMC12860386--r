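Package: plmmfit
Title: Penalized Linear Mixed Models for Correlated High-Dimensional Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits sparse penalized linear mixed models for high-dimensional
    regression when observations are correlated through latent structure such
    as population stratification, batch effects, or cryptic family
    relatedness. The relatedness matrix K = (1/p) X X' is estimated from the
    standardized features themselves, the model is preconditioned (rotated)
    by the inverse square root of the estimated covariance so that errors on
    the rotated scale are independent, and lasso, MCP, SCAD, and elastic-net
    regressions are fit along a regularization path by coordinate descent.
    Prediction uses the best linear unbiased predictor (BLUP), and k-fold
    cross-validation repeats every preprocessing step (standardization,
    relatedness, variance components, rotation) inside each fold. PLINK 1
    binary filesets and delimited text matrices are supported as input, with
    an optional file-backed storage mode so the full genotype matrix is
    never resident in memory.
License: GPL-3
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
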