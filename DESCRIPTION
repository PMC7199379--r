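Package: trendscreen
Title: Trend-Correlation Feature Screening for Ultrahigh-Dimensional
    Categorical Data with Binary Response
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Marginal and iterative sure independence screening for
    case-control studies with very many ordinal categorical features,
    such as genome-wide SNP genotype matrices. Implements the trend
    correlation screening statistic (TC-SIS) and its iterative extension
    (ITC-SIS), which interleaves screening with residual projection onto
    the orthogonal complement of already-selected features to break
    linkage-disequilibrium confounding. Includes the benchmark marginal
    screeners based on distance correlation, Pearson chi-squared
    (Cramer's V squared) and marginal maximum likelihood, Monte-Carlo
    simulation designs for power and model-size evaluation, and a
    two-stage analysis pipeline (minor-allele-frequency filtering,
    cross-validated first-step size selection, joint multiple logistic
    regression) for genotype matrices in delimited-text or PLINK .raw
    format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    glmnet
Config/testthat/edition: 3
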