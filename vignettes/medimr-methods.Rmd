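---
title: "Methods: two-sample MR screening and mediation with medimr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR screening and mediation with medimr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medimr)
```

## The problem

Two-sample Mendelian randomization (MR) uses genetic variants as
instrumental variables to estimate the causal effect of an exposure (here:
a circulating protein or metabolite) on an outcome (a binary disease trait
such as lung adenocarcinoma), from nothing but per-SNP GWAS summary
statistics of two non-overlapping studies. `medimr` implements the full
screening workflow: instrument selection, allele harmonization, a
five-estimator battery, sensitivity diagnostics, evidence tiering across
many exposures, reverse MR, and two-step mediation MR with bootstrap
inference — together with a synthetic-GWAS generator that makes every stage
testable against known ground truth.

The validity of any MR estimate rests on three instrument assumptions:
(1) relevance — the variant is robustly associated with the exposure;
(2) independence from confounders of the exposure–outcome relation;
(3) exclusion restriction — the variant affects the outcome only through
the exposure. Violations of (3) are *pleiotropy*; most of the machinery in
this package exists to detect or withstand it.

## Instrument selection

Three sequential filters, each with a complete audit trail
(`selectInstruments()`):

* **Association**: retain SNPs with exposure p-value strictly below a
  threshold. The default is `1e-5`, the relaxed cutoff commonly used for
  molecular traits when too few SNPs reach the genome-wide `5e-8`.
* **Independence**: greedy LD clumping (`ldClump()`) — repeatedly take the
  most significant remaining SNP as an index and remove candidates within
  ±10,000 kb on the same chromosome whose squared correlation with it is
  ≥ 0.001. The `≥` comparison means the default prunes essentially all
  correlated pairs. The window is two-sided, matching common clumping
  tools; ties on p-value break lexicographically by SNP id so the output
  never depends on input order. LD comes from an explicit correlation
  matrix supplied by the caller (the synthetic module provides one); the
  package does not download reference panels.
* **Strength**: per-SNP explained variance
  `R² = 2·MAF·(1−MAF)·β²` with `MAF = min(EAF, 1−EAF)`, and
  `F = R²(N−2)/(1−R²)`; SNPs with `F < 10` are excluded (strictly:
  `F = 10` is retained). When a SNP's own sample size is missing, a
  study-level fallback can be supplied; SNPs without allele frequency
  cannot be scored and are excluded with an audit record.

## Harmonization

`harmonize()` expresses both studies' effects for the exposure's effect
allele. Matching orientations copy; swapped orientations negate the
outcome beta and complement its allele frequency. Palindromic SNPs (A/T,
C/G) cannot be strand-resolved from alleles alone: those with exposure MAF
≥ 0.42 are dropped as ambiguous, while below that threshold allele
frequency disambiguates (an outcome EAF on the opposite side of 0.5
indicates a strand flip). Pairs matching neither orientation are dropped
as mismatches. No strand-complement rescue is attempted for
non-palindromic SNPs — an A/G exposure against a C/T outcome is treated as
a mismatch rather than silently complemented. Every requested SNP is
either retained or dropped with a reason, never lost silently.

## The estimators

All estimators operate on per-SNP Wald ratios `r_j = beta_out/beta_exp`
with first-order delta-method standard errors `se_j = se_out/|beta_exp|`
(the dominant convention; a second-order option including the exposure SE
is available but off by default).

* **IVW** (primary): `Σ w_j r_j / Σ w_j` with `w_j = 1/se_j²`,
  algebraically the weighted least-squares slope of outcome on exposure
  betas through the origin. The default model is multiplicative random
  effects: the fixed-effect SE is inflated by `max(1, sqrt(Q/(k−1)))` and
  never deflated, a conservative choice given heterogeneity is the rule in
  molecular-trait MR; a pure fixed-effect model is a switch away.
* **MR-Egger**: weighted regression with a free intercept; the slope is
  the causal estimate under the InSIDE assumption and the intercept
  estimates the average directional pleiotropy. Rows are first oriented so
  all exposure betas are non-negative — without that convention the
  intercept has no meaning, a point on which published descriptions are
  often silent. Perfect fits (zero residual variance) report NA p-values
  with an explicit `degenerate_fit` flag rather than infinite statistics.
* **Weighted median**: the ratio at which cumulative normalized
  inverse-variance weight crosses one half, using the centred convention
  `p_j = (S_j − w_j/2)/S_k` with linear interpolation; tied ratios are
  merged (weights summed) first, which makes the estimate invariant to
  duplicating SNPs. Consistent while valid instruments carry ≥ 50% of the
  weight.
* **Simple and weighted mode**: the mode of a Gaussian kernel density of
  the ratios (equal or inverse-variance weights), bandwidth
  `φ·0.9·min(sd, mad)·k^(−1/5)` (modified Silverman rule, `φ = 1` by
  default). Consistent when the largest group of instruments sharing an
  estimate is the valid one.

Median and mode SEs come from a seeded parametric bootstrap (each ratio
resampled from `Normal(r_j, se_j)`, default 1000 replicates; the seed is a
mandatory argument — there is no hidden global RNG state). P-values are
two-sided normal throughout; 95% CIs use 1.96 on the log-odds scale before
exponentiating to odds ratios. The published worked example is reproduced
exactly by this arithmetic: a log-odds of −0.2454 maps to OR 0.7824, and
the p-value recomputed from the reported interval (0.6169–0.9923) is
0.0430.

## Sensitivity diagnostics

* **Cochran's Q** (`cochranQ()`): `Σ w_j (r_j − β_IVW)²` about the
  fixed-effect centre (the standard definition, even when the main fit is
  random-effects), chi-square on `k−1` df, with per-SNP contributions that
  sum to Q exactly.
* **Egger intercept test**: re-exports the regression intercept triple; a
  small p-value flags directional pleiotropy.
* **Leave-one-out** (`leaveOneOut()`): the IVW fit recomputed omitting
  each SNP in turn, plus the all-SNP row.
* **PRESSO-style outlier test** (`mrPresso()`): a re-implementation of the
  pleiotropy residual-sum-and-outlier idea from its published description,
  simplified to the intercept-free IVW residual framework (no
  two-parameter grid search). The observed statistic is the weighted
  leave-one-out residual sum of squares; its null distribution is
  simulated parametrically (default 1000 draws), each SNP gets a simulated
  tail probability Bonferroni-corrected by `k`, and a distortion test
  compares the post-removal estimate shift against random removals of the
  same size. All simulated p-values use add-one smoothing
  `(count+1)/(nSim+1)`, so they are never exactly zero and are bounded
  below by `1/(nSim+1)`. A practical corollary: the corrected per-SNP
  p-value cannot fall below `k/(nSim+1)`, so outlier detection at level
  0.05 needs `nSim > 20·k`.

## Screening and evidence tiers

`mrScreen()` runs each exposure through the full pipeline, never aborting
on a per-exposure failure (a failed exposure yields a `tier = "none"` row
carrying the reason). Evidence tiers follow the consistency of the five
estimators at significance level 0.05: no tier without a significant IVW;
"inclusion" when IVW alone is significant; "strong" with 2–3 significant
methods; "very strong" with ≥ 4. We read the tier rule as requiring IVW
significance for *any* tier — the alternative reading (counting methods
regardless of the primary) would label an exposure "strong" on the
strength of secondary estimators alone, which contradicts the primary-
method logic of the workflow; the brute-force enumeration oracle in the
tests pins this resolution. Benjamini–Hochberg q-values are reported
across exposures' IVW p-values but tiering is on raw p-values by default
(mirroring the screening practice the workflow reproduces), with a config
switch. Reverse MR (`reverseMr()`) swaps the roles and reruns the same
pipeline; a forward finding with a non-significant reverse is labelled
unidirectional.

## Two-step mediation MR

`twoStepMediation()` estimates the total effect α (exposure → outcome),
β1 (exposure → mediator, on the exposure's instruments) and β2
(mediator → outcome, on the mediator's instruments). Before the β2 leg,
mediator instruments associated with the exposure (p < 1e-5) are removed
(`excludeExposureSnps()`): we operationalize "conditioning on the
exposure" as instrument exclusion rather than multivariable MR, which is
declared out of scope — with summary statistics only, exclusion is the
transparent choice and the threshold is configurable. The indirect effect
is the product β3 = β1·β2 and the proportion mediated is β3/α, reported
exactly (never truncated to [0,1]; a sign disagreement between β3 and α is
flagged `opposite_sign_proportion` rather than hidden). Inference on β3
is by parametric bootstrap — the only resampling available with summary
data: each leg's outcome-side betas are redrawn from `Normal(beta, se)`,
the IVW slopes refitted, and the product recorded; CI by 2.5/97.5
percentiles, p-value `2·min(P(β3* ≤ 0), P(β3* ≥ 0))` with add-one
smoothing. Defaults (1000 replicates, percentile CI) are package choices;
the workflow this reproduces does not state its bootstrap settings.

## The synthetic-GWAS generator

`simulateMrStudy()` emits exposure, mediator and outcome summary studies
with known truth, simulating summary statistics directly (no
individual-level genotypes — desk-scale speed, with calibration verified
by the test suite):

* True instrument effects `γ_j ~ N(0, 0.1)` — strong, protein-QTL-scale
  instruments (F of order 100 at the default n = 50,000), so the strongest
  easily clear p < 1e-5.
* Observed betas add noise with the standard error approximation
  `1/sqrt(2·EAF·(1−EAF)·n)`; EAF uniform on [0.05, 0.95] keeps SEs finite.
  Binary-outcome betas are treated as log-odds with the same
  approximation; prevalence modelling is out of scope.
* Mediator betas are `β1·γ_j + δ_j`, outcome betas
  `(θ + β1·β2)·γ_j + β2·δ_j + α_j`, where `δ_j` are mediator-specific
  instrument effects (zero by default; required for the mediator → outcome
  leg to be estimable at all) and `α_j` are direct (pleiotropic) effects:
  zero, balanced `N(0, sd)`, or directional. Directional pleiotropy and
  planted gross outliers act relative to the exposure-increasing allele
  (multiplied by `sign(γ_j)`); with allele-agnostic direct effects, the
  orientation step any Egger fit requires would turn directional
  pleiotropy into balanced and the intercept test would have nothing to
  detect.
* SNPs sit on one chromosome in equicorrelated LD blocks (blocks 25 Mb
  apart — always beyond the 10,000 kb clumping window — and 5 kb spacing
  inside); sampling noise is correlated accordingly and `ldMatrix()`
  returns the exact block-diagonal correlation matrix.
* Identical configs (including the seed) give byte-identical output, and
  the generator restores the caller's RNG state.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: realistic allele-frequency spectra,
case-control ascertainment, sample overlap between studies, population
stratification, and LD with off-block structure. It validates the
*estimators and pipeline logic*, not the epidemiology of any particular
dataset.

## Numerical and design choices

* P-values are floored at the smallest positive double rather than
  underflowing to zero, preserving the (0, 1] contract and order.
* Recovery checks in the tests compare the mean of replicate estimates to
  the planted value within three SDs of the replicate distribution.
  Estimators there run on the generator's true-instrument list: selecting
  instruments at p < 1e-5 from the same data being analysed induces
  winner's-curse attenuation (about 10% at these settings), a genuine
  property of one-sample selection rather than of the estimators. The
  screening tests exercise the full selection path, where only ranking and
  significance matter.
* Problem sizes in the test and acceptance runs (50-instrument panels,
  200–1000 Monte-Carlo replicates, 1000-draw bootstraps) were chosen to
  keep the whole validation suite in the low minutes on one CPU while
  leaving Monte-Carlo error well below the tolerances tested.
* Screen determinism: per-exposure bootstrap seeds derive from the
  exposure's study id, not its list position, so screens are invariant to
  input order; all writers emit fixed column orders and full-precision
  numerics, making repeated runs byte-identical.
* The package reads and writes GWAS-SSF-style delimited tables (tab or
  comma auto-detected) with configurable column maps; VCF-encoded summary
  statistics, genome-build liftover and multi-allelic sites are out of
  scope.

## Known limitations

Instrument selection and estimation on the same exposure study inherits
winner's curse, as in any two-sample MR with in-sample selection; no
Steiger filtering or proxy-SNP lookup is provided; the PRESSO-style test
is a simplified re-implementation, not the reference two-parameter
procedure; and reverse MR on a purely mediated outcome signal will pick up
the exposure's instruments (the reason directionality filters exist) — it
is informative only when the outcome has instruments of its own.
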