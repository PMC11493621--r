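Package: mrmediate
Title: Two-Sample Mendelian Randomization with Two-Step Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics, oriented towards two-step mediation designs such as
    gut microbiota -> immune cell -> disease chains. Provides readers for
    GWAS-Catalog-, FinnGen- and generic-style summary-statistic tables,
    allele harmonization, instrument selection (p-value threshold, greedy
    LD clumping, per-instrument R-squared and F-statistic weak-instrument
    filtering), five causal estimators (inverse-variance weighted, MR-Egger,
    weighted median, weighted mode, and a Bayesian weighted model with
    outlier down-weighting), heterogeneity and horizontal-pleiotropy
    diagnostics with leave-one-out analysis, batch bidirectional screening
    with significance tiering, product-of-coefficients mediation
    decomposition, and a seeded synthetic summary-statistics generator with
    known causal truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
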