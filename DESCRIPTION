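Package: mrflow
Title: Two-Sample Mendelian Randomization with Pleiotropy Diagnostics,
    Meta-Pooling and Mediation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization (MR) workflow for
    GWAS summary statistics: instrument selection and quality control
    (genome-wide significance, minor-allele-frequency and palindromic-variant
    filters, region exclusion, greedy LD clumping), allele harmonization,
    instrument-strength diagnostics (F statistics, variance explained, I2GX,
    sample-overlap bias approximation), five causal estimators (Wald ratio,
    fixed- and multiplicative-random-effects inverse-variance weighting,
    MR-Egger with intercept test, weighted median, weighted mode), the
    MR-PRESSO global, outlier and distortion tests, Steiger directionality
    filtering, fixed-effects meta-pooling of outcome datasets, multivariable
    MR, and two-step MR mediation with bootstrap confidence intervals.
    Includes a summary-statistic simulator with known ground truth for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
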