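Package: mrmediate
Title: Two-Sample Mendelian Randomization with Two-Step Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Instrument selection, harmonization, and estimation machinery for
    two-sample Mendelian randomization (MR) from GWAS summary statistics:
    genome-wide significance filtering, greedy LD clumping, confounder-based
    instrument exclusion and F-statistic screening; inverse-variance-weighted
    (fixed and multiplicative random effects), MR-Egger, weighted-median and
    multivariable MR estimators; MR-PRESSO outlier detection; Cochran's Q
    heterogeneity diagnostics; and a two-step multivariable-MR mediation
    decomposition (direct, indirect, proportion mediated). Includes a seeded
    generator of synthetic GWAS summary statistics with controllable causal
    structure, pleiotropy and instrument strength for calibration and
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
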