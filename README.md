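# trigmr

Phenome-wide two-sample Mendelian randomization (MR) for a continuous
lipid exposure — plasma triglyceride (TG) levels — against many binary
disease outcomes, for statistical geneticists and epidemiologists working
from GWAS summary statistics rather than individual-level data.

Genetic variants robustly associated with TG serve as instrumental
variables: under the relevance, independence and exclusion-restriction
assumptions, the SNP-outcome effect $\Gamma_j$ and SNP-exposure effect
$\gamma_j$ satisfy $\Gamma_j = \theta\,\gamma_j$, where $\theta$ is the
causal log odds ratio per 1 SD of exposure. The workhorse estimator is
the fixed-effect inverse-variance weighted (IVW) regression through the
origin,

$$\hat\theta \;=\; \frac{\sum_j w_j \hat\beta_{Xj}\hat\beta_{Yj}}
                        {\sum_j w_j \hat\beta_{Xj}^2},
\qquad
\mathrm{SE}(\hat\theta) = \Big(\sum_j w_j \hat\beta_{Xj}^2\Big)^{-1/2},
\qquad w_j = \hat\sigma_{Yj}^{-2},$$

surrounded by the standard sensitivity suite for horizontal pleiotropy:
MR-Egger regression (intercept = directional pleiotropy test), the
weighted median estimator, MR-PRESSO global and per-SNP outlier tests
with IVW refitting, and multivariable MR to separate TG from correlated
lipid fractions (LDL-C, HDL-C, ApoB). Results are reported as odds
ratios per 1 SD TG with 95% CIs.

The package provides:

* **I/O** — versioned tab-delimited dialects for GWAS summary statistics,
  LD (r²) reference panels and result tables (`read_sumstats()`,
  `read_ld_panel()`, `write_results()`).
* **Instrument selection** — genome-wide filtering and deterministic
  PLINK-convention greedy LD clumping (`select_genome_wide()`,
  `ld_clump()`; defaults p1 = 5e-8, p2 = 5e-4, r² = 0.05, 250 kb), and
  allele harmonization with palindromic-SNP frequency resolution
  (`harmonize()`).
* **Estimators** — `wald_ratio()`, `ivw_fixed()`, `mr_egger()`,
  `weighted_median()`, `mvmr_ivw()`, `presso_global()`,
  `presso_outlier()`, `presso_refit()`.
* **Phenome pipeline** — discovery scan across an outcome manifest,
  replication of nominally significant mappable traits with an
  independent instrument set, Bonferroni-based three-tier evidence labels
  (BB / BN / NB / none), sensitivity and MVMR passes, and reverse MR
  (`run_discovery()`, `run_replication()`, `assign_tiers()`,
  `run_sensitivity()`, `run_mvmr_pass()`, `run_reverse()`).
* **Synthetic data** — a generator of paired exposure/outcome summary
  statistics for two non-overlapping cohorts with known causal effect,
  configurable pleiotropy, planted outliers and block LD
  (`sim_params()`, `simulate_two_sample()`, `simulate_phenome()`,
  `simulate_ld_panel()`), used throughout the tests as ground truth.

## Worked example

Simulate a small phenome (8 binary outcomes, 3 with a true effect
θ = 0.25, 10% pleiotropic SNPs), select instruments, and run the
discovery–replication–tier pipeline:

```r
library(trigmr)

params <- sim_params(m = 141, theta = 0.25, pi_pleio = 0.1, seed = 2024)
ph     <- simulate_phenome(params, k_outcomes = 8, k_causal = 3)

instr <- select_genome_wide(ph$exposure_discovery)   # 138 of 141 pass 5e-8
disc  <- run_discovery(instr, ph$manifest)
head(disc$results[, c("trait_id", "n_snps", "or_", "ci_low", "ci_high", "pvalue")], 4)
#>   trait_id n_snps  or_ ci_low ci_high    pvalue
#> 1 trait002    138 1.32 0.2525  0.3026 1.85e-104
#> 2 trait001    138 1.30 0.2352  0.2853  4.67e-92
#> 3 trait003    138 1.26 0.2072  0.2573  1.04e-73
#> 4 trait005    138 1.03 0.0015  0.0516  3.78e-02

repl  <- run_replication(select_genome_wide(ph$exposure_replication),
                         disc$results, ph$manifest)
tiers <- assign_tiers(disc$results, repl$results,
                      n_discovery_tests = 8, n_replication_tests = repl$n_tested)
tiers[tiers$tier != "none",
      c("trait_id", "pvalue_discovery", "pvalue_replication", "tier")]
#>   trait_id pvalue_discovery pvalue_replication tier
#> 1 trait002        1.85e-104           1.26e-53   BB
#> 2 trait001         4.67e-92           4.18e-56   BB
#> 3 trait003         1.04e-73           4.07e-62   BB
```

The three simulated causal traits — and only those — replicate at the
Bonferroni level in both cohorts (tier BB). The odds ratios (1.26–1.32
per 1 SD TG) are `exp` of the IVW estimates, which recover θ = 0.25 up
to sampling noise. Sensitivity analyses on a tiered trait:

```r
sens <- run_sensitivity(tiers, disc$sets, mr_config(seed = 7))
b <- sens[["trait001"]]
#> Egger slope 0.251 (intercept p = 0.80), weighted median 0.252,
#> PRESSO global p = 0.626
```

With balanced pleiotropy the Egger intercept and PRESSO global tests are
quiet, and all estimators agree with the IVW estimate — the pattern that
distinguishes benign from distorting pleiotropy.

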