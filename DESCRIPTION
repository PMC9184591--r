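Package: cfbgwas
Title: Baseline Adjustment in Pharmacogenomic GWAS of Quantitative Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying baseline adjustment in
    genome-wide association studies (GWAS) of change-from-baseline drug-response
    phenotypes. Provides a generative model for baseline and post-treatment
    responses with genotype, treatment and genotype-by-treatment effects and
    multiplicative measurement error; twelve regression-based association models
    (two-step inverse-normal-transformed residual and one-step formulations,
    1df and 2df Wald tests, and Cochran's Q heterogeneity test); Monte-Carlo
    machinery for empirical type I error and power with margin-of-error
    inflation criteria; and per-variant genome-scan diagnostics (genomic
    inflation factor, QQ data, mediator-enriched variant subsets).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    optparse,
    parallel,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
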