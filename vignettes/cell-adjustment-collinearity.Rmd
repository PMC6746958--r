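---
title: "Cell-type adjustment, multicollinearity and sign reversal in methylation models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type adjustment, multicollinearity and sign reversal in methylation models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collinearEwas)
```

## The problem

Whole-blood DNA methylation is a mixture signal: each leukocyte subtype has
its own methylation profile, so inter-individual differences at a CpG partly
reflect differences in cell composition. The standard correction is to
estimate six cell proportions (CD8 T, CD4 T, NK, B, monocytes, granulocytes)
by reference-based deconvolution and enter them as covariates in the
methylation–phenotype regression. Two facts make that dangerous:

1. the six proportions are near-compositional (they approximately sum to
   one), so they are strongly mutually correlated by construction; and
2. for inflammation-related phenotypes such as adiposity, CpG methylation
   itself can be highly correlated with cell composition.

Both violate the classical OLS assumption of no multicollinearity. The
consequences are inflated standard errors, unstable coefficients, and — when
the marginal and partial associations differ in sign — an apparent reversal
of the direction of association. This package implements the whole study
loop: simulate a cohort with the relevant correlation structure, fit the
model families, diagnose the collinearity, try the usual remediations, and
measure the reversal frequency by Monte Carlo against a closed-form oracle.

## The model families

All models are ordinary least squares with log-transformed BMI as the
outcome (BMI is right-skewed) and percent methylation at one CpG as the
exposure, adjusted for age and sex:

* **unadjusted**: `log BMI ~ CpG + age + sex`
* **six-cell**: adds all six estimated proportions
* **five-cell**: adds five, omitting granulocytes (the highest-VIF cell)
* **PC-substituted**: adds the first *k* principal components of the six
  proportions instead of the proportions themselves
* **residualized**: regresses the methylation values on cell proportions
  first (singly or jointly) and uses the residuals as the exposure.

Coefficients are reported per one percentage-point of methylation, with
classical standard errors, t-based 95% intervals and per-model complete-case
counts: every fit drops exactly the rows missing one of *its own* variables,
so each CpG has its own n. Sign reversal between two fits is flagged only
for strictly opposite signs — an exactly zero coefficient carries no sign.

Two algebraic identities are asserted in the tests because they carry the
scientific point that full-rank remediations cannot help. Substituting all
six PC scores is an invertible linear reparameterization of the adjustment
set, so the CpG coefficient is unchanged; and by the Frisch–Waugh–Lovell
theorem, regressing the outcome on methylation residualized against the
full covariate set (age, sex, six cells) reproduces the six-cell-model
coefficient exactly. Remediation can therefore only change the estimate by
changing the model — dropping information — never by re-expressing it.

## The synthetic cohort generator

`defaultRaineLikeSpec()` encodes the study conditions: n = 812 participants,
nine CpGs in one differentially methylated region, six cell proportions, and
a 16-variable joint Gaussian correlation matrix pinned to the published
anchors — the CpG4-by-cell Pearson correlations (0.611, 0.553, 0.371, 0.215,
−0.402, −0.783), the outcome–granulocyte correlation (0.16), and per-CpG
outcome correlations recovered from the unadjusted association summaries via
`correlationFromT()` (r = t/√(t² + df), giving ≈ −0.10 for CpG4). Per-CpG
missingness rates reproduce the published complete-case counts (e.g. a 4%
rate leaves ≈ 780 of 812 complete).

The unpublished parts of the correlation matrix are completed by a
two-factor latent construction:

* **M**, a shared cell-composition/inflammation axis: CpG4 loads 0.95, each
  cell type loads its target correlation divided by 0.95 (so the pinned
  CpG4–cell entries hold exactly), and the other CpGs load in proportion to
  their published correlation with the first cell-proportion PC, capped at
  CpG4's loading;
* **Q**, a cell-only factor with loadings (0.65, 0.70, 0.55, 0.50, 0.45,
  −0.55), expressing the near-closure of deconvolution estimates:
  granulocytes are almost determined by the other five cells.

We deliberately complete the matrix through factors rather than by literally
sampling `gran = 1 − sum(others) + noise`: a construction with independent
latent cells cannot support a CpG correlated at +0.61/+0.55 with two cells
and −0.78 with a third (the implied quadratic form exceeds one, so no joint
distribution exists). The factor construction is positive definite by
construction for the pinned blocks (smallest eigenvalue 0.049 for the
default matrix, no repair needed), hits every printed target exactly, and
still reproduces the compositional signatures that matter: granulocytes
anti-correlated with the lymphoid fractions, the mean six-proportion sum
close to (and slightly above) 1, and a granulocyte VIF an order of magnitude
above the acceptable range. User-supplied matrices that are not positive
definite fail loudly by default; an opt-in `repair` flag applies a
nearest-positive-definite projection and reports the Frobenius distance
moved.

Means and SDs are *placeholders*, fully configurable and documented as such:
BMI log-normal with median 22 kg/m² (SD 0.15 on the log scale), methylation
50% ± 3.75, cell means (0.08, 0.18, 0.05, 0.06, 0.09, 0.55) with SDs
(0.025, 0.055, 0.015, 0.018, 0.025, 0.077). The methylation SD was chosen so
that, combined with r ≈ −0.10, the unadjusted coefficient lands near
−0.004 per percentage point, the published magnitude; none of the
collinearity or reversal behaviour depends on these location/scale choices.
Age is Normal(17, SD 0.25) and sex Bernoulli(0.5), independent of
everything; proportions and methylation are clipped to [0, 1] and [0, 100],
which at the default parameters touches < 0.1% of draws and biases no cell
mean by more than 0.01 (asserted by test). Missingness is completely at
random per CpG — the varying published per-CpG counts motivate the feature,
but no mechanism beyond MCAR is claimed.

What the generator does *not* emulate: beta-value distributions bounded in
[0, 1] with heteroscedastic noise (we use Gaussians on the percent scale),
batch effects, deconvolution estimation error correlated across samples, or
any genuine biological causal structure. Passing tests therefore show that
the statistical phenomenon — compositional collinearity producing sign
reversal — is faithfully reproduced, not that any particular real cohort
behaves identically.

## Diagnostics

`computeVif()` computes each predictor's VIF from its own auxiliary
regression on all other predictors (with intercept), over the predictor set
actually entered in the model; the intercept never receives a VIF. Tolerance
is 1/VIF and `pctVarianceExplained()` is (1 − 1/VIF)·100; a VIF of 5
(80%) is the conventional ceiling. Exactly collinear predictors yield an
infinite VIF with a warning record rather than an error, so array-scale
sweeps do not abort. `conditionIndices()` scales the design columns to unit
length and reports the largest singular value over each singular value,
ascending.

`correlationMatrix()` reports Pearson or Spearman (average-rank) estimates
with pairwise complete-case counts and two-sided p-values from the t
approximation `t = r√((n−2)/(1−r²))`; the approximation is used at all n
for tractability at array scale. `highCorrelationScreen()` streams CpGs in
configurable chunks so memory stays flat at 450k scale, counts CpGs with
|r_s| at or above the threshold (0.700 by default) per cell type, and skips
a cell type whose sample SD falls below 1e-6 (mirroring screens that omit
essentially-constant NK estimates) with a logged notice.

## The Monte-Carlo sign-reversal experiment

`runSignReversalExperiment()` draws replicated trivariate Gaussian cohorts
of (outcome, methylation, granulocyte) and fits per replicate OLS of outcome
on methylation (plus granulocyte when included), recording the sign of the
methylation coefficient. The defaults are the study conditions: n = 812,
1,000 replicates, r(methylation, granulocyte) = −0.783,
r(outcome, granulocyte) = 0.16, and r(outcome, methylation) ≈ −0.10 derived
from the printed coefficient and CI (the study did not print this
correlation; it is exposed as a parameter). `sweepCorrelations()` re-runs
the scenario grid (−0.783, −0.5, −0.25, and a granulocyte-omitted baseline)
on independent seeded substreams derived from one master seed by fixed
offsets. The simulated regressions contain no age/sex terms, matching the
three-variable design; the cohort pipeline covers the full model.

The closed-form oracle `analyticSignProbability()` evaluates
Φ(ρ_p·√n / √(1 − ρ_p²)) with ρ_p the partial (or, without granulocyte,
marginal) correlation — a large-n normal approximation whose error is
O(1/n), negligible at n ≥ 500. Under the defaults it gives 88.0%, 25.3%,
3.7% and 0.2% for the four scenarios; the Monte-Carlo fractions agree
within three Monte-Carlo standard errors across a 12-spec grid (asserted by
test). Exact-zero coefficients count as non-positive; the fraction positive
is invariant to the means/SDs because coefficient signs are invariant to
positive affine rescaling of the variables (asserted by running the same
seed at two scale settings).

## Numerical conventions

* OLS is solved by pivoted QR; exact rank deficiency raises an error naming
  the aliased columns (VIF reporting, by contrast, returns +Inf).
* PCA uses `prcomp` (centered, unscaled by default — the scaling choice is
  exposed since conventions differ) with a deterministic sign convention:
  each component's largest-magnitude loading is positive.
* Degenerate inputs fail loudly: non-positive BMI before the log transform,
  constant predictors in VIF/correlation computations, residualized
  methylation that is numerically constant, zero design columns.
* Seeds: every stochastic entry point takes an explicit integer seed;
  scenario substreams use fixed small offsets from the master seed.

## Problem sizes used in the checks

The test suite exercises cohorts of n = 812 (the study condition) with a
single n = 100,000 cohort for correlation-recovery checks (Monte-Carlo SE of
a correlation ≈ 0.003, against a ±0.02 band), Monte-Carlo runs of 1,000
replicates at n = 500–812, and a 1,000-CpG × 1,000-participant screen
fixture with 50 constructed high-correlation CpGs. These sizes make every
stochastic assertion a ≥ 3-sigma check while keeping a full run in well
under a minute per file.

## Known limitations

* The generator's Gaussian-with-clipping proportions are a deliberate
  simplification; a logit or Dirichlet construction would bound proportions
  naturally but make the pinned Pearson targets non-interpretable.
* The reported VIF pattern (granulocyte VIF > 10, all five-cell VIFs < 5)
  is a qualitative reproduction; the extreme published values (VIF ≈ 114)
  depend on the closure noise of real deconvolution estimates, which is not
  identifiable from the printed correlations alone.
* Spearman p-values rely on the t approximation even at small n.
* The per-CpG missingness model is MCAR; informative missingness would
  change complete-case behaviour in ways the package does not model.
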