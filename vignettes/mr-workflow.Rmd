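---
title: "Two-sample Mendelian randomization with mrflow: models, design choices and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrflow)
```

## The problem

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure (here, a circulating biomarker such as 25-hydroxyvitamin D,
analysed in standard-deviation units after rank-based inverse-normal
transformation) on a disease outcome (a binary trait such as migraine,
analysed on the log-odds scale) using only GWAS summary statistics from two
non-overlapping samples. Each genetic instrument $j$ contributes an
estimated exposure effect $\hat\gamma_j$ (SE $\sigma_{Xj}$) and outcome
effect $\hat\Gamma_j$ (SE $\sigma_{Yj}$); under the instrumental-variable
assumptions every valid instrument satisfies
$\Gamma_j = \theta\,\gamma_j$, and the package's job is to estimate
$\theta$, defend the estimate against pleiotropy and reverse causation,
and decompose it through a mediator.

## Instrument construction

`filter_instruments()` applies the standard selection ladder sequentially:
genome-wide significance ($p < 5\times10^{-8}$), minor allele frequency
$\min(\mathrm{eaf}, 1-\mathrm{eaf}) \ge 0.01$, removal of multiallelic
variant ids, removal of palindromic (A/T, C/G) variants whose strand is
ambiguous, and exclusion of designated regions. The HLA region is shipped
as `hla_region()`, interpreted as chromosome 6, positions 25,000,000 to
34,000,000 as a 1-based *closed* interval — the source for such exclusions
is conventionally given in megabases only, and the closed reading is the
conservative one. The audit counts removed records per filter, and the
counts plus the retained count always equal the input count.

`clump()` is greedy: repeatedly take the remaining variant with the
smallest p-value and discard every remaining variant on the same chromosome
within the window whose $r^2$ with it exceeds the threshold (defaults
$r^2 < 0.01$, 10,000 kb). Ties on p-value break by lexicographic variant
id, so output is deterministic. The LD matrix is an input; the package does
not compute LD from genotype panels.

`harmonize()` aligns outcome records onto the exposure's effect allele.
Because palindromic variants are excluded upstream (the default policy
drops any that remain), allele matching may ignore strand: a swapped or
complement-swapped pair flips the sign of the outcome effect and replaces
its allele frequency by one minus itself; anything else is dropped and
counted. Harmonization is idempotent.

## Estimators

All estimators consume the harmonized set. Writing $w_j = 1/\sigma_{Yj}^2$:

* **IVW** — weighted regression through the origin,
  $\hat\theta = \sum w_j\hat\gamma_j\hat\Gamma_j / \sum w_j\hat\gamma_j^2$.
  The multiplicative random-effects (MRE) variant, the primary model,
  scales the fixed-effects SE by $\sqrt{\phi}$ with
  $\phi = Q/(J-1)$, where $Q$ is Cochran's statistic of the residuals.
  $\phi$ is deliberately *not* floored at 1 for IVW (the pure
  multiplicative model), while MR-Egger's overdispersion *is* floored at 1;
  both conventions follow the most widespread implementations and are
  stated here because implementations differ.
* **MR-Egger** — weighted least squares with an intercept after orienting
  every instrument to a non-negative exposure effect; the intercept
  estimates directional pleiotropy, and its test is the standard check for
  unbalanced horizontal pleiotropy under the InSIDE assumption. Inference
  uses the t distribution with $J-2$ degrees of freedom (honest at the
  3-SNP minimum); IVW p-values use the normal distribution.
* **Weighted median** — interpolated median of the per-SNP Wald ratios
  $\hat\theta_j = \hat\Gamma_j/\hat\gamma_j$ under first-order
  inverse-variance weights $(\hat\gamma_j/\sigma_{Yj})^2$; consistent when
  instruments carrying a majority of weight are valid.
* **Weighted mode** — argmax of the weighted Gaussian kernel density of the
  ratios, bandwidth $0.9\,\min(\mathrm{sd}, \mathrm{mad})\,J^{-1/5}$
  (the mad term skipped when zero) times a `bandwidth_factor` (default 1),
  maximized on a grid spanning the ratios padded by $3h$ at resolution
  $h/10$, ties broken toward the smaller value.
* **Wald ratio** — the single-SNP building block, with the first-order
  delta-method SE $\sigma_{Yj}/|\hat\gamma_j|$ that ignores exposure-side
  uncertainty. This is the dominant convention and a documented
  limitation; it is accurate when $\sigma_{Xj}/|\hat\gamma_j|$ is small,
  which the F > 30 selection guarantees here.

Median and mode SEs come from a seeded parametric bootstrap (default 1,000
replications) that redraws both summary effects from normal distributions
at their reported SEs; every stochastic component in the package takes an
explicit seed and is bit-reproducible.

Degenerate inputs are handled explicitly: exactly proportional (noise-free)
data give $\phi = 0$ and a collapsed confidence interval rather than an
error; a zero exposure effect invalidates the Wald ratio with a clear
message; estimators refuse sets below their minimum instrument count.

## MR-PRESSO

`mr_presso()` implements the residual-sum-and-outlier framework: for each
SNP the IVW slope is re-fitted with that SNP left out, giving an observed
weighted squared residual; the total is compared against simulated datasets
drawn from the fitted values at the reported SEs. Empirical p-values use
the add-one convention $(1+k)/(N+1)$ so they are never zero. Per-SNP
outlier p-values are Bonferroni-thresholded at $0.05/J$, flagged SNPs are
removed for the outlier-corrected MRE estimate, and the distortion test
compares the induced shift against random removals of the same size. The
default 1,000 simulations bound the smallest attainable p at about
$10^{-3}$, which equals the Bonferroni threshold near $J = 50$; analyses
of larger sets should raise `n_simulations` (the calibration studies below
use 2,000 at $J = 51$). One behaviour worth knowing: a gross outlier
inflates the leave-one-out slopes of *clean* SNPs while the simulated null
is outlier-free, so a strongly contaminated set occasionally co-flags a
clean SNP alongside the true outlier; since flagged SNPs are simply removed
before re-estimation, this costs a little efficiency, not validity.

## Directionality

Steiger filtering guards against reverse causation. Instrument-trait
squared correlations come from the t-to-r conversion
$r^2 = t^2/(t^2 + n - 2)$; for the binary outcome the same formula is
applied on the logistic scale, an approximation (the liability-scale
conversion is a possible refinement), with total sample size as the
effective n — the simplest defensible choice, stated openly. The test
Fisher-transforms both correlations and compares them with variance
$1/(n-3)$ per side. Retention requires the exposure correlation to be
strictly larger (ties are removed) *and* a Steiger p below 0.01. The
reverse workflow is the same machinery with roles swapped.

## Pooling, multivariable MR and mediation

`pool_datasets()` performs fixed-effects inverse-variance meta-analysis of
per-SNP outcome effects across non-overlapping datasets, after aligning
alleles exactly as in harmonization. Pooling is associative; SNPs missing
from some datasets are pooled over the rest with a presence mask recorded
(dropping them instead would destabilize instrument counts); SNPs with
irreconcilable alleles are dropped with an audit entry. No genomic-control
or heterogeneity correction is applied at this step.

`mvmr_ivw()` regresses outcome effects on the $J \times K$ matrix of
exposure effects (no intercept, weights $w_j$), with overdispersion
$\mathrm{RSS}/(J-K)$ floored at 1. The instrument panel for multivariable
analyses is the union of each exposure's instruments restricted to SNPs
present in all datasets. Two-step mediation multiplies the
exposure-to-mediator IVW estimate ($\beta_1$) by the exposure-adjusted
mediator-to-outcome MVMR estimate ($\beta_2$); the bootstrap CI draws the
two stages independently (they come from non-overlapping regressions),
reporting percentile bounds of $\exp(\beta_1^*\beta_2^*)$ over 10,000
seeded draws, and the proportion mediated is the signed ratio of indirect
to total effect.

## The synthetic study

`simulate_two_sample()` generates the package's test bed, emulating the
statistical structure of a large vitamin-D-style exposure GWAS against a
migraine-style case-control outcome. Defaults, chosen once: 184 independent
instruments; exposure GWAS of 417,580 individuals on a variance-1
(rank-normalized) scale; outcome GWAS of 589,356 individuals at case
fraction 0.0831; true causal effect $\ln(0.916) = -0.0877$ log-odds per SD;
total explained variance 4%; MAF uniform on (0.05, 0.5). Per-SNP F
statistics are drawn as $30 + \mathrm{Exp}(\text{mean }60)$ — the floor
matches the genome-wide-significance edge and the mean (~92) is what a 4%
PVE across 184 instruments at this sample size implies — then rescaled so
the realized PVE hits the target exactly. Generation is entirely at the
summary level: reported estimates are the latent truths plus normal noise
at the analytic SEs, $\sigma_X = (2\,\mathrm{maf}(1-\mathrm{maf})\,n)^{-1/2}$
for the quantitative exposure and the case-control analogue with the extra
$\varphi(1-\varphi)$ factor for the binary outcome.

Pleiotropy regimes: a configurable fraction of instruments receives direct
outcome effects $\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)$, optionally
correlated with instrument strength through a Gaussian copula
(`rho_inside`, an InSIDE violation when nonzero); gross outliers add a
configurable multiple of the outcome SE; reverse-causal SNPs are generated
outcome-first, with the outcome effect sized by a target F statistic and
the exposure effect a configurable fraction of it. A truth record stores
every latent quantity so bias and coverage are computable exactly.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: linkage disequilibrium between instruments
(instruments are independent by construction; `simulate_ld_blocks()`
exists only to exercise clumping), winner's-curse inflation from selecting
instruments in the same sample, the single extreme-effect loci that give
real vitamin-D GWASs F statistics in the thousands, sample overlap between
exposure and outcome GWASs (the overlap-bias approximation is validated by
a separate one-sample simulation), population stratification, and
liability-scale subtleties of the binary trait.

The mediation chain (`simulate_mediation_chain()`) adds a calcium-like
mediator: 210 mediator-specific instruments from a GWAS of 300,000
individuals explaining 2% of the mediator, stage effects 0.0504
(exposure to mediator) and 0.0601 (mediator to outcome), direct path
$-0.0908$, so the total is $-0.0878$ and about 3.4% of it flows through
the mediator. The stage-2 outcome dataset has 750,000 individuals at case
fraction $68{,}597/750{,}000$; its published counterpart reports the case
count but not the total, so the total is a realistic choice made once.

## Calibration results the test suite computes

The acceptance suite (`tests/testthat/test-acceptance.R`) and the
acceptance script (`scripts/acceptance.R`) recompute, from scratch at the
sizes above: mean IVW bias below 0.005 log-odds with 95% CI coverage
inside [0.92, 0.975] over 500 replicates; Egger intercept type-I error
inside [0.03, 0.07] under balanced pleiotropy ($\sigma_\alpha = 0.005$,
500 replicates); weighted-median bias under one third of the IVW bias when
40% of instruments carry directional effects of genuine-risk-locus size
($\mu_\alpha = 0.08$ log-odds — chosen because the median's finite-sample
bias saturates at the ratio-noise quantile shift, so the comparison is only
informative once contamination pushes IVW well past that floor); MR-PRESSO
flagging a planted 10-$\sigma$ outlier in at least 95 of 100 seeded runs
and nothing in at least 90 of 100 clean runs; at least 90% of planted
reverse-causal SNPs removed by Steiger filtering with at most 2% false
removals; and bit-identical reruns of every stochastic component under a
fixed seed. Problem sizes (200–500 replicates, 50–184 SNPs) keep the whole
suite under a minute on one core while leaving Monte-Carlo error well
inside the asserted bands.

## Orchestration

`analysis_config()` plus `run_analysis()` execute the whole design per
outcome: the estimator battery and MR-PRESSO at the primary level, then the
sensitivity ladder — (1) excluding a supplied pleiotropic-SNP list (built
from covariate-GWAS lookups in a real analysis, fabricated with known
contaminants by the generator), (2) Steiger filtering, (3) both — followed
by the pooled-outcome analysis, mediation, and the reverse analysis. The
ladder only ever removes SNPs, so instrument counts are non-increasing
across levels. Significance labelling is two-tier (default 0.017 = 0.05/3
Bonferroni-strict and 0.05 nominal); a p-value exactly at a threshold falls
into the weaker tier, a boundary rule stated here because conventions
differ. `render_report()` emits one row per outcome, sensitivity level and
method, every number taken from the stored estimate objects, and reruns
are byte-identical; the numbered scripts under `analysis/` drive the same
functions over a simulated study.

## Known limitations

Wald-ratio SEs ignore exposure-side uncertainty (first-order NOME
convention); the binary-trait Steiger conversion is logistic-scale, not
liability-scale; the sample-overlap bias formula is a first-order $1/F$
approximation validated by simulation only at moderate instrument
strength; conditional F statistics for multivariable MR and winner's-curse
corrections are out of scope; and duplicate variant ids in an input are
resolved by keeping none of the copies (the multiallelic filter), a policy
choice the underlying study designs leave unstated.
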