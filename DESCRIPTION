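Package: mrdirect
Title: Univariable and Multivariable Two-Sample Mendelian Randomization
    for Direct Effects of Correlated Exposures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates total and direct causal effects of two genetically
    correlated exposures on a binary outcome from GWAS summary statistics,
    in the two-sample Mendelian randomization framework. Implements
    fixed- and multiplicative-random-effect inverse-variance-weighted
    estimation, MR-Egger regression with the directional-pleiotropy
    intercept test, the weighted-median estimator with parametric
    bootstrap standard errors, multivariable MR for direct effects with
    conditional F-statistics and the Q_a pleiotropy diagnostic, Cochran's
    Q and between-stratum heterogeneity tests, analytic power for
    binary-outcome MR, and a seeded generator of synthetic two-sample
    summary statistics (with an individual-level simulation path used as
    an oracle). Motivated by life-course analyses that separate the
    effect of early-life body size from adult body size on colorectal
    cancer risk.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
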