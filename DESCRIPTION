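Package: summr
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization (MR) toolkit for
    GWAS summary statistics: instrument selection with F-statistic and
    variance-explained scoring, greedy LD clumping, allele harmonization
    with palindromic-variant handling, the inverse-variance-weighted,
    MR-Egger, weighted-median and weighted-mode causal estimators,
    heterogeneity diagnostics (Cochran's Q, I-squared, Rucker's Q, the
    Egger intercept deviation test and an MR-PRESSO global/outlier test),
    Steiger directionality, binary-outcome power and detectable-effect
    calculations, multivariable IVW adjustment for correlated co-exposures,
    and a seeded synthetic summary-statistic generator so every stage of a
    bidirectional exposure-outcome study can be verified at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
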