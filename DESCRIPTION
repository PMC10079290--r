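Package: trigmr
Title: Phenome-Wide Two-Sample Mendelian Randomization for Plasma Triglycerides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for phenome-wide two-sample Mendelian
    randomization (MR) of a continuous lipid exposure, such as plasma
    triglyceride levels, against many binary disease outcomes. Provides
    genome-wide instrument selection with greedy LD clumping, allele
    harmonization of exposure and outcome summary statistics, fixed-effect
    inverse-variance weighted (IVW) estimation, MR-Egger regression, the
    weighted median estimator, MR-PRESSO global and per-variant outlier
    tests with IVW refitting, multivariable MR controlling for correlated
    lipid fractions, reverse MR, and a three-tier Bonferroni
    discovery/replication classification. A synthetic summary-statistics
    generator with known causal effects, horizontal pleiotropy, planted
    outliers and block LD supports calibration and parameter-recovery
    testing without access to individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
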