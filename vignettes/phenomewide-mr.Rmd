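---
title: "Phenome-wide two-sample Mendelian randomization: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenome-wide two-sample Mendelian randomization: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trigmr)
```

## The causal model

trigmr estimates the causal effect of a continuous exposure — plasma
triglyceride (TG) levels, measured in SD units — on binary disease
outcomes, using genetic variants as instrumental variables in a two-sample
design: SNP–exposure associations come from one GWAS cohort and
SNP–outcome associations from a second, non-overlapping cohort. For SNP
$j$, let $\gamma_j$ be its true effect on the exposure and $\Gamma_j$ its
true effect on the outcome (log odds ratio). Under the instrumental-variable
assumptions (relevance, independence, exclusion restriction),

$$\Gamma_j = \theta\,\gamma_j,$$

where $\theta$ is the causal log-OR per 1 SD of exposure. Horizontal
pleiotropy breaks the exclusion restriction by adding a direct effect
$\alpha_j$, giving $\Gamma_j = \theta\gamma_j + \alpha_j$. Every estimator
in the package is a different way of recovering $\theta$ from the observed
effect pairs $(\hat\beta_{Xj}, \hat\beta_{Yj})$ while tolerating different
patterns of $\alpha_j$:

* **Wald ratio** (single SNP): $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$
  with the first-order SE $\hat\sigma_{Yj}/|\hat\beta_{Xj}|$, which ignores
  exposure-side uncertainty. With strong instruments the neglected term is
  second-order; the small attenuation it causes is visible only at
  Monte-Carlo precision (see the recovery results).
* **Fixed-effect IVW**: weighted regression of $\hat\beta_Y$ on
  $\hat\beta_X$ through the origin, weights $w_j = \hat\sigma_{Yj}^{-2}$:
  $\hat\theta = \sum w_j \hat\beta_{Xj}\hat\beta_{Yj} / \sum w_j
  \hat\beta_{Xj}^2$ and $\mathrm{SE} = (\sum w_j \hat\beta_{Xj}^2)^{-1/2}$.
  The fixed-effect form keeps the residual variance at 1 — the discovery
  estimator, maximising power when pleiotropy is absent. A multiplicative
  random-effects variant (residual variance floored at 1) is available via
  `ivw_fixed(random_effects = TRUE)`.
* **MR-Egger**: the same weighted regression with a free intercept, after
  recoding each SNP so $\hat\beta_{Xj} \ge 0$ (Egger is not invariant to
  allele coding, so the orientation is fixed internally). The intercept
  estimates average directional pleiotropy and its p-value is the
  pleiotropy test; the slope is a causal estimate that remains consistent
  under directional pleiotropy if instrument strength is independent of the
  direct effects (InSIDE). SEs use the residual variance floored at 1.
* **Weighted median**: the weighted 50th percentile of the per-SNP Wald
  ratios, weights proportional to $\hat\beta_{Xj}^2/\hat\sigma_{Yj}^2$
  (the first-order inverse ratio variance), consistent when at least half
  the weight comes from valid instruments. The percentile interpolates
  linearly between the two ratios bracketing cumulative weight 0.5 (with
  the conventional half-weight offset, so equal weights reproduce the plain
  median). The SE is the SD of a seeded parametric bootstrap.
* **MR-PRESSO**: residual-sum-of-squares outlier machinery. The observed
  statistic is $\sum_j (\hat\beta_{Yj} - \hat\theta_{(-j)}
  \hat\beta_{Xj})^2$ with $\hat\theta_{(-j)}$ the IVW estimate leaving SNP
  $j$ out; its null distribution comes from parametric simulation
  (resampling both effect sides from normals centred on the leave-one-out
  fit, and recomputing the leave-one-out slopes on each simulated data
  set). P-values use the add-one estimator $(1 + k)/(n_{\mathrm{sim}}+1)$,
  so they are never zero and always lie on a lattice. Per-SNP outliers are
  called below a corrected threshold, by default $0.05/m$; IVW is refit
  without them when the global test is significant. The distortion test is
  deliberately not implemented.
* **Multivariable IVW**: weighted regression of $\hat\beta_Y$ on the
  $m \times K$ matrix of exposure effects without intercept, estimating
  each exposure's direct effect conditional on the others — used here to
  separate TG from correlated lipid fractions (LDL-C, HDL-C, ApoB) in four
  nested models.

## The phenome scan

`run_discovery()` applies intersect–harmonize–IVW to every outcome in a
manifest, isolating per-trait failures as skipped rows rather than
aborting a scan of thousands of traits. `run_replication()` re-tests
traits that were at least nominally significant ($p<0.05$) and are
mappable between cohorts, deliberately using an instrument set selected
from a *second* exposure GWAS — the three-dataset design that diversifies
the instrument source. `assign_tiers()` then classifies each trait by
Bonferroni (B) versus nominal-only (N) significance in the two stages: BB
(Bonferroni in both), BN (Bonferroni discovery, nominal replication), NB
(nominal discovery, Bonferroni replication), otherwise none. Thresholds
are $\alpha/n$ for the stated test counts; with $\alpha = 0.05$ and 2600
discovery, 221 replication and 141 instrument tests these are
$1.92\times10^{-5}$, $2.26\times10^{-4}$ and $3.55\times10^{-4}$. Only
Bonferroni is offered — no FDR — and no cross-cohort meta-analysis is
performed, because tier labels, not pooled estimates, are the scan's
output. Reverse MR (`run_reverse()`) swaps the roles, running the full
selection pipeline on the disease GWAS; diseases without at least two
clumpable genome-wide-significant SNPs are reported as not testable
rather than failing.

## Instrument selection and harmonization

Instruments are genome-wide-significant SNPs ($p<5\times10^{-8}$) pruned
to near-independence by greedy LD clumping with the PLINK-convention
parameters `--clump-p1 5e-8 --clump-p2 5e-4 --clump-r2 0.05 --clump-kb
250` as defaults. Candidates are visited in ascending p-value order; ties
break lexicographically by SNP id so results are identical across
platforms (PLINK's internal order is not reproducible from a text
description). The window is measured from the index SNP and SNPs on other
chromosomes are never pruned.

Harmonization aligns each outcome record to the exposure's effect allele:
matching alleles pass through, swapped alleles negate the outcome beta,
and complementary-strand encodings are complemented first. Palindromic
SNPs (A/T, C/G) cannot be strand-resolved from alleles alone; they are
kept only when both effect-allele frequencies are informative — outside
`[limit, 1 - limit]` with the default limit 0.42, a common MR convention —
and the frequencies then decide the orientation. Ambiguous palindromic
and irreconcilable records are dropped and counted in the instrument
set's provenance fields. No LD-proxy lookup is attempted for instruments
missing from an outcome dataset: the design restricts to shared SNPs.
Whether palindromic filtering should precede or follow clumping is not
determined by the design; the package harmonizes after selection, which
keeps selection a pure function of the exposure GWAS.

## What the synthetic generator emulates

`simulate_two_sample()` draws, per SNP: allele frequency $f_j \sim
U(0.05, 0.5)$; true exposure effect $\gamma_j$ with random sign and
magnitude $U(0.02, 0.08)$ SD per allele; standard errors from the
standardised-trait approximations $\sigma_{Xj} = (n_X 2f_j(1-f_j))^{-1/2}$
and, on the log-OR scale with case fraction $\phi$, $\sigma_{Yj} = (n_Y
\phi(1-\phi) 2f_j(1-f_j))^{-1/2}$; and independent normal noise on the two
sides (non-overlapping cohorts). Defaults $n_X = 3\times10^5$, $n_Y =
1.7\times10^5$, $\phi = 0.5$ put ~98% of instruments past genome-wide
significance, emulating the strong-instrument regime of a large lipid
GWAS; the magnitude range is configurable because no empirical effect-size
distribution is being matched. Pleiotropy enters as $\alpha_j$, zero with
probability $1-\pi$ and otherwise normal with mean $\mu_\alpha +
\rho\,(\gamma_j/\mathrm{sd}(\gamma))\,\sigma_\alpha$ — $\mu_\alpha$
controls balanced versus directional pleiotropy and $\rho$ breaks InSIDE.
Planted outlier SNPs always receive a direct effect, which is then
multiplied by `outlier_multiplier`; without that rule an outlier drawn in
the non-pleiotropic mass would get $10 \times 0 = 0$ and the
outlier-detection contracts would be vacuous. LD is represented only in
the reference panel (block-diagonal $r^2$, blocks > 250 kb apart), not in
the effect estimates, because the pipeline clumps to near-independence
before any estimation; correlated-instrument estimation is out of scope.
`simulate_phenome()` shares one SNP architecture across two exposure
cohorts and all outcomes, with per-trait seeds derived deterministically
from the master seed so phenome runs are reproducible trait by trait.

What the generator does *not* emulate — realistic allele-frequency
spectra, LD-correlated effect estimates, sample overlap, selection of
instruments via a third independent dataset, phenotype-ontology mismatch
— bounds what passing tests show: they validate the estimators and the
scan logic under the stated statistical model, not performance on real
biobank data.

## Numerical and design choices

* 95% CIs use the normal quantile 1.96, matching the reporting
  convention of MR forest plots; odds ratios are `exp(beta)` per 1 SD.
* Duplicate SNP ids keep the record with the smallest p (the clump
  preference); a `drop_multiallelic` switch removes sites with several
  allele pairs instead, since how such sites were pre-filtered upstream is
  generally unknowable from summary statistics.
* Weighted fits behind MR-Egger and MVMR go through `stats::lm`; the
  coefficient covariance is rebuilt from the normal equations so that the
  variance floor applies cleanly (and exact fits do not divide by a zero
  residual variance). The test suite checks all of them against
  hand-coded normal-equation oracles.
* Egger and the weighted median require a stated seed; the bootstrap and
  PRESSO simulations restore the caller's RNG state, so a surrounding
  simulation stream is never perturbed by a sensitivity pass.
* The PRESSO per-SNP and global tests share one set of simulated draws;
  `n_sim` defaults to 1000, the smallest count whose add-one p-values can
  fall below the 141-instrument corrected threshold
  ($1/1001 < 3.55\times10^{-4}$).
* MVMR's rank guard names the offending exposures; it can be disabled,
  in which case aliased exposures come back as `NULL` rather than fake
  zeros.
* Calibration facts, each recomputed by `scripts/acceptance.R` and the
  test suite: IVW type-I error under the null is exact by construction
  (the z-statistic is pivotal given the exposure effects) and measures
  ~4–5% over 1000 replicates; the Egger intercept test with the floored
  variance measures ~5% over large replications under no pleiotropy. Under
  *balanced* pleiotropy the intercept test runs anticonservative (~8% at
  $\pi = 0.3$, $\sigma_\alpha = 0.01$) because additive pleiotropy
  variance is misspecified under multiplicative $1/\sigma_Y^2$ weighting —
  a known property of the convention, worth remembering when reading
  pleiotropy p-values near 0.05.
* Monte-Carlo problem sizes used by the suite and the acceptance script —
  200 replicates for recovery means, 500 for calibration rates, 1000 for
  type-I error, 100 for outlier detection, 50 phenomes of 50 traits for
  the null-scan check — were chosen to give standard errors comfortably
  inside each check's tolerance while keeping a full run in well under a
  minute of simulation time.

## Limitations

The Wald/IVW SEs ignore exposure-side uncertainty, giving a small
attenuation (~0.3% of $\theta$ at the default instrument strength) that
is real but negligible against the CIs reported. Instruments are selected
in the same exposure GWAS used for estimation, so winner's curse
contributes a further small attenuation, most visible in the
reverse-MR path where selection is part of the pipeline; no correction is
applied. The binary-outcome SE formula is a balanced-design approximation
— adequate because only relative weights matter to every estimator here.
Tier classification inherits the usual caveat that Bonferroni counts are
analysis choices, not properties of the data.
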