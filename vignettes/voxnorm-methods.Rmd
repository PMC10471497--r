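---
title: "Normative modelling of voxel-wise brain morphometry with voxnorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative modelling of voxel-wise brain morphometry with voxnorm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxnorm)
```

## The problem

Early-life adversity leaves long-term traces in brain structure, but those
traces are subtle, regionally specific, and superimposed on large individual
differences in brain growth and ageing. Normative modelling addresses this the
way pediatric growth charts do for height: a reference model predicts a
morphometric measure from covariates, and each person is characterised by
where they fall relative to the predictive distribution, rather than by a
group-mean contrast.

voxnorm implements this programme voxel-wise for tensor-based morphometry.
The measure at each voxel is the (log) Jacobian determinant (JD) of a
nonlinear registration's deformation field — local volume expansion versus
contraction. Two reference models are provided:

* an **adversity model**: Bayesian linear regression (BLR) of each voxel's JD
  on a panel of adversity scores plus sex and total intracranial volume
  (TIV), fitted under 10-fold cross-validation;
* a **lifespan model**: age (B-spline basis), sex and site, with a
  sinh-arcsinh (SHASH) residual distribution so that skewed, heavy-tailed
  morphometric variation yields calibrated growth-chart centiles.

Downstream, adversity-specific contributions are summarised by structure
coefficients and their spatial overlap (dice on top-2% maps), the adversity
panel is compressed into varimax-rotated principal components, and per-subject
deviation maps (`z`-scores thresholded at ±2.6) are summarised into burdens
that enter linear mixed models of longitudinal anxiety.

Because the cohorts such analyses run on are not publicly distributable, the
package ships synthetic-cohort generators that emulate the relevant structure
of the data. Every pipeline stage is exercised and tested end-to-end on these
synthetic cohorts.

## The Bayesian linear regression engine

For a voxel with outcome vector $y \in \mathbb{R}^n$ and design $X$
(adversities, sex, TIV; continuous columns standardised with training-fold
statistics, binary columns left 0/1, plus an intercept):

$$y = Xw + \varepsilon, \qquad \varepsilon \sim N(0, \beta^{-1} I), \qquad
w_j \sim N(0, \alpha^{-1})$$

with the intercept effectively unpenalised (fixed prior precision $10^{-8}$,
the growth-chart convention that the reference level is not shrunk). The
posterior is Gaussian with covariance $S = (A + \beta X^\top X)^{-1}$ and mean
$m = \beta S X^\top y$. The hyperparameters $(\alpha, \beta)$ maximise the log
marginal likelihood (evidence), optimised over $(\log\alpha, \log\beta)$ by
L-BFGS-B with analytic gradients, two fixed starts ($(0,0)$ and $(-2,2)$),
box bounds $\pm 30$, and a $10^{-6}$ objective tolerance; voxels that do not
converge are flagged in a QC table, never silently dropped.

Predictions carry both noise and coefficient uncertainty,
$\sigma_*^2 = 1/\beta + x_*^\top S x_*$, so deviations
$z = (y - \hat y)/\sigma_*$ shrink toward zero where the model is uncertain —
deliberately conservative. Model accuracy per voxel is the Pearson
correlation $\rho$ between observed and predicted values and the standardised
mean squared error, $\mathrm{SMSE} = \overline{(y-\hat y)^2} \big/
\overline{(y-\bar y)^2}$; the population-variance denominator makes the
training-mean predictor score exactly 1. Explained variance is
$1 - \mathrm{SMSE}$.

Cross-validation uses a seeded balanced random permutation into $k = 10$
folds (no stratification); every subject's prediction, and hence z-score,
comes from the fold that held that subject out, and the $\rho$/SMSE maps are
computed from these pooled cross-validated predictions. Pooling (rather than
averaging per-fold metrics) was an open choice; it uses every subject exactly
once and keeps the metric defined even in small folds.

## The lifespan centile model

The ageing model is, per voxel,

$$y = Xw + \tau\, u, \qquad \mathrm{warp}_{\epsilon,\delta}(u) \sim N(0, 1),
\qquad \mathrm{warp}_{\epsilon,\delta}(u) = \sinh(\delta \sinh^{-1}(u) - \epsilon),$$

where $X$ contains a cubic B-spline basis over age (5 interior knots equally
spaced on the observed age range — configurable; the knot scheme is a package
choice), a sex indicator and reference-coded site indicators. The warp acts
on the $\tau$-standardised residual, keeping $(\epsilon, \delta)$ scale-free:
$\epsilon$ controls skew, $\delta > 0$ tail weight, and $(0, 1)$ recovers the
Gaussian model exactly. Covariate effects (including site offsets) stay
additive on the measurement scale.

Estimation is direct joint maximum likelihood over
$(w, \log\tau, \epsilon, \log\delta)$ with analytic gradients (L-BFGS-B),
started from the Gaussian BLR solution at the identity warp and from a
skewness-informed warp start. We initially implemented the textbook
alternation — Gaussianise residuals, refit by BLR, re-profile the scale — but
its fixed point solves a quasi-likelihood estimating equation that differs
from the true SHASH score and produced centile location biases of up to 0.2
residual sd at realistic sample sizes; the joint optimiser is both exact and
faster. At the optimum, an evidence-optimised BLR on the Gaussianised
pseudo-outcome supplies the coefficient posterior used to inflate predictive
uncertainty.

Centile curves at level $q$ for a covariate profile $x_*$ are

$$C_q(x_*) = x_*^\top m + \tau\,
\mathrm{warp}^{-1}_{\epsilon,\delta}\!\left(\Phi^{-1}(q)\, s_*\right),
\qquad s_*^2 = 1 + x_*^\top S x_* / \tau^2 .$$

Because the inverse warp is strictly increasing, curves at increasing levels
cannot cross. The default level set is the conventional seven
(1/5/25/50/75/95/99%). Model evaluation uses a split-half holdout stratified
by site and sex (all sites must appear in training), scoring the median
prediction on the original scale; `holdout = "none"` fits the full sample for
parameter-recovery experiments, with metrics then flagged as in-sample.

## Adversity-specific maps

Raw adversity scores of very different granularity are harmonised by ordinal
binning: at most 4 bins, each with at least 10 subjects, cuts only between
distinct raw values. We place cuts by an exact dynamic programme over
distinct-value boundaries that attains the maximal feasible bin count and,
among feasible placements, the most even occupancy. (A simpler
quantile-cut-and-merge scheme collapses to too few bins on lopsided
distributions — e.g. a binary score split 15/20 — because the quantile order
statistics all land on one value.) Binning is monotone, so effect directions
are preserved; an unbinned variant is a configuration toggle.

Each adversity's contribution is its **structure coefficient**: the
correlation, over subjects, between the raw predictor and the model's
cross-validated prediction at each voxel. Under collinearity — adversities
co-occur by construction — structure coefficients remain interpretable where
partial regression weights do not. Spatial specificity is quantified by
thresholding each adversity's map at the top 2% (positive and negative tails
separately; ties broken deterministically by value then voxel index) and
computing pairwise dice overlap $2|A \cap B|/(|A|+|B|)$, reported per sign,
averaged, and on the sign-pooled union (which of these the field's reported
"whole-brain overlap" uses is not standardised, so all are returned).
Model variants (with/without TIV, binned/unbinned, dropped adversities, or
two time points) are compared by the voxel-wise Pearson correlation of their
metric maps with a Fisher-z two-sided p-value.

## Multivariate adversity factors

Because adversities co-occur, the panel is also summarised by PCA on the
correlation matrix with varimax rotation (`stats::varimax`, tolerance
$10^{-8}$), keeping 3 components by default. Loading-column signs are fixed
so the largest-magnitude loading is positive, making output reproducible
across linear-algebra backends. Rotated scores are scaled to have variance
equal to the rotated component variance, so model predictions sampled at
points of the standardised score scale multiplied by the square root of the
eigenvalue land on the score scale actually entering the design. Slope maps
per component are predictions at 4 sampling points (default: the
5/35/65/95% quantiles of the standardised scores; a seeded random mode is
available since a random-sampling reading of the procedure is equally
defensible) expressed relative to the all-zero-score baseline with sex and
TIV at sample means; for this linear engine all sampling points give the
same slope, which the tests exploit as an invariant.

## Deviations and psychopathology

Per-subject cross-validated z-maps are thresholded at $|z| > 2.6$ (one-sided
tail probability $< 0.005$), split by sign into volume contractions
($z < -2.6$) and expansions ($z > +2.6$). The default per-subject burden is
the supra-threshold voxel count per sign (a mean-|z| variant is provided; the
field's exact summary is not standardised). Burdens — typically zero-inflated
counts — are Box-Cox transformed toward normality, with $\lambda$ maximising
the profile log-likelihood (golden-section search; a shift of $1 - \min(x)$
is applied and recorded when zeros are present).

Anxiety at two assessment waves is modelled by a linear mixed model with a
random intercept per subject (REML via lme4), fixed effects for the
transformed burden and time, and optional covariates. Two-sided p-values use
a normal approximation on the t-ratios by default, with Satterthwaite degrees
of freedom (lmerTest) behind a flag; partial $\eta^2$ is $t^2/(t^2 + df)$.
With one observation per subject the random intercept is unidentifiable and
the model intentionally degenerates to OLS with a warning. The significance
level is Bonferroni-corrected over 4 psychopathology outcomes × 2 deviation
signs, $0.05/8 = 0.00625$; an explicit override is accepted for analyses
whose pre-registered corrected level differs (0.008 is in circulation for
this design, and the package asserts neither as canonical).

## What the synthetic cohorts emulate

**Adversity cohort.** Seven adversity scores follow a Gaussian copula: a
latent exchangeable-correlation normal (default 0.3 — a moderate positive
co-occurrence; the true inter-adversity correlation matrix of any given
cohort is a free parameter, not something the generator claims to reproduce)
transformed per variable so each marginal matches published-cohort-style
ranges, means and standard deviations (e.g. maternal smoking 0–2,
mean 0.36, sd 0.71; trauma 25–63, mean 29.6, sd 5.92). Continuous scores are
censored normals, count scores discretised normals, both with latent
parameters calibrated by closed-form moment matching so the target moments
are hit exactly in expectation. Sex is Bernoulli(0.58) (the typical female
fraction of the reference cohort) and TIV is positive on an mm³ scale.

**JD images.** A ground-truth `effect_atlas` assigns each predictor a 3D
coefficient map; images are $y_v = \sum_j \beta_{vj} x_j + \varepsilon_v$
with independent Gaussian voxel noise. The default grid is 12×12×12 with an
ellipsoidal mask (≈500 voxels) — large enough for spatial overlap statistics,
small enough for desk-scale tests; planted effects occupy contiguous blocks
with alternating sign so both expansions and contractions exist.

**Lifespan cohort.** Ages uniform on 8–97 years, nine sites with planted
additive offsets, a rise-and-fall median age trajectory (Gaussian bump plus
linear decline), and SHASH residuals (default $\epsilon = 0.5$: right-skewed,
so the identity-warp Gaussian model is genuinely misspecified while the
warped model is correctly specified).

**Psychopathology.** Anxiety at two waves follows a random-intercept model
driven by the negative-deviation burden, censored at zero to mimic a 0–14
symptom checklist; defaults (intercept 2.8, random-intercept sd 1.0,
residual sd 1.5) put scores on that checklist's scale. For end-to-end power
experiments the planted slope (0.3 per burden voxel) is chosen so the burden
effect carries a partial $\eta^2$ near 0.10 — the magnitude reported for this
design in the literature — at a 12³ grid's burden scale; published
per-voxel slopes (≈0.07) belong to million-voxel burdens and have no
analogue on a desk-scale grid.

What these generators do **not** emulate: real brain anatomy and spatial
autocorrelation of deformation fields (voxels are independent given the
design), registration artefacts, site differences beyond additive offsets,
missing-data mechanisms, and purposive sampling designs. Passing tests
therefore demonstrate statistical correctness of the estimators and pipeline
plumbing, not robustness to the full messiness of imaging data.

All randomness descends from one integer master seed through fixed per-stage
offsets (`child_seed`), so any pipeline stage can be reproduced in isolation
and full reruns are bit-identical; the pipeline manifest records the
configuration and MD5 hashes of every output.

## Numerical choices and degenerate inputs

* Evidence optimisation: bounds $e^{\pm 30}$ on both precisions keep the
  noiseless-data limit ($\beta \to \infty$) finite; rank-deficient designs
  are an error, not a warning.
* Ages outside the spline's range are clamped with a warning at prediction
  time; unknown site labels are an error.
* `threshold_top` tie-break: stable order by (value, voxel linear index).
* Dice of two empty maps is defined as 0 with a warning.
* Box-Cox of a constant vector returns the identity with a warning;
  constant outcomes and constant predictors are flagged (`NA` metrics), not
  errors, in map-level summaries.
* Problem sizes in the test-suite experiments (e.g. 10 × 50-voxel cohorts of
  n = 500 for z-calibration; 10 end-to-end runs of n = 300 on the 12³ grid;
  n = 2000, 20 voxels for centile recovery) were chosen as the smallest sizes
  at which the statistical properties under test are stable, keeping the
  default suite complete on a laptop.

## Known limitations

* Voxels are modelled independently; no spatial regularisation or smoothing.
* No site harmonisation beyond fixed effects, and no transfer of a fitted
  model to unseen sites.
* The SHASH family is the two-parameter $(\epsilon, \delta)$ shape family
  around a learned location/scale; richer warps (e.g. compositions) are not
  implemented.
* Only dimensional psychopathology outcomes are modelled — no diagnostic
  categories, mediation, or causal claims.
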