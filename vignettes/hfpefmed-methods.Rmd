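---
title: "Methods: subtype-specific nonlinear mediation for HFpEF myocardial work"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subtype-specific nonlinear mediation for HFpEF myocardial work}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the models, the estimands, the numerical choices, what the synthetic world
does and does not establish, and the design decisions that were genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The problem

HFpEF cohorts mix at least two phenotypes — a younger cardiorenal one
(severe renal dysfunction, neurohormonal activation, pronounced mechanical
dyssynchrony) and an older cardiac one (preserved renal function, less
dyssynchrony). Peak strain dispersion (PSD, ms), the standard deviation of
time-to-peak longitudinal strain across 18 LV segments, is a candidate
*mediator*: upstream clinical factors (eGFR, BNP) may degrade myocardial
work outcomes — global wasted work (GWW, mmHg%) and global work efficiency
(GWE, %) — partly *through* dyssynchrony. The pipeline therefore (i)
discovers subtypes, (ii) quantifies which features predict GWW/GWE, and
(iii) decomposes exposure effects into direct and PSD-mediated parts,
separately per subtype.

## 2. Mediation: model, estimand, inference

Within an analysis subset (usually one subtype), with every continuous
variable z-scored (sample, n−1 denominator), three OLS models are fit:
Model 1 `Y ~ X + C` (total effect c), Model 2 `M ~ X + C` (path a), and
Model 3 `Y ~ X + M + C` (direct effect c′, path b), where `C` is the
adjustment set (default: age, sex, HTN, DM, CAD, RD, SBP, DBP, LVMI, LVEF,
GLS).

**Estimand.** The indirect effect is the difference-method estimate
`c − c′`. With shared covariates and no nonlinear terms this equals `a·b`
*exactly* — an algebraic identity of nested least squares, not an
approximation — and the suite asserts it to 1e−8 on arbitrary data. When
squared (`X²`, `M²`) or interaction (`X·M`) terms are enabled there is no
single "the" coefficient, so the package commits to an explicit estimand:
the **average partial derivative** of the fitted surface with respect to
the exposure over the analysis sample, computed numerically with step
0.01 SD. This collapses to the plain coefficient in the linear case; for
the interaction model it equals the derivative at the sample-mean mediator
(zero, after z-scoring), because the derivative is linear in M.

**Mediation ratio.** `(c − c′)/c`, reported as missing (never ±Inf) when
|c| < 1e−12, and flagged when inconsistent mediation (opposite-signed
direct and indirect parts) pushes it past 100% — ratios above 100% are a
real phenomenon, not an error.

**Bias-corrected bootstrap.** Rows of the analysis set are resampled with
replacement; each replicate replays the *entire* estimation pipeline —
re-standardizing the continuous variables within the resample before
refitting Models 1 and 3. This matters: the reported estimator is a
standardized (correlation-like) quantity whose sampling variance is
smaller than that of a raw coefficient, and bootstrapping pre-standardized
rows was observed during development to over-cover (100% at nominal 95%
in the calibration simulation); re-standardizing per replicate restores
nominal coverage (measured 0.96 at n = 400, B = 500, 200 repeats, with
type-I error 0.055 at nominal 0.05). With `z0 = qnorm(F̂(θ̂))`, the CI
takes the `pnorm(2 z0 ± z_{α/2})` percentiles of the replicate
distribution (type-7 quantiles); the fraction below the point estimate is
clamped to (1/(B+1), B/(B+1)) so z0 stays finite. Replicates with
rank-deficient designs are dropped and counted; more than 10% failures
aborts with a diagnostic rather than reporting a fragile interval.

**Grid conventions.** `run_grid()` treats clinical factors (eGFR, BNP) as
exposures and PSD as the mediator — the direction in which the headline
results are stated — though every role is configurable. Two pragmatic
guards: RD (the renal-dysfunction flag) is dropped from the covariates
when eGFR is the exposure (they are near-collinear by construction), and
binary covariates whose within-subtype minority count is below 5 are
dropped with a warning, because such columns are constant in a substantial
fraction of bootstrap resamples and would trip the 10% failure abort for
a purely mechanical reason.

## 3. Subtyping

K-means uses k-means++ initialization and Lloyd iteration, best of
`n_init` restarts by within-cluster SSE, on the z-scored eight-variable
block (age, BMI, eGFR, BNP, LVEF, LAVI, E/e′, PSD). Empty clusters are
re-seeded at the farthest point and counted. k is selected by mean
silhouette over k ∈ 2..6 with ties broken toward smaller k (parsimony
stands in for "clinical interpretability"). Stability is the
prediction-strength construction: resample rows, refit, assign *all*
original points to the nearest resampled centroid, and compute the ARI of
that partition against the reference clustering. Because the ARI is
invariant under label permutation, the centroid-matching relabeling step
sometimes described for this procedure is a mathematical no-op and is
omitted. A caution from development: on a structureless isotropic blob the
stability ARI is low (~0.3) in the 8-dimensional analysis space but can
exceed 0.6 in 2-D, where best-of-restarts k-means keeps re-finding the
same noise-determined split axis — stability should always be judged
against a null of matching dimension.

Group comparison mirrors the clinical-table convention: Shapiro–Wilk at
α = 0.05 in *both* groups gates Welch's t (mean ± sd) versus Mann–Whitney
U (median (Q1–Q3)); binary variables use chi-square, switching to Fisher's
exact test when any expected cell is below 5. Constant variables are
flagged, not tested.

## 4. Prediction and attribution

`build_features()` appends five clinically motivated products (PSD×LVEF,
age×HTN, eGFR×BNP, RWT×E/e′, GLS×LVMI). By default parents and target are
z-scored *before* multiplying, so no term dominates a regularized fit and
reported RMSEs live on the standardized scale (raw mode is kept for
sensitivity analysis). The suite runs ridge (closed-form solve; exactly
OLS as λ→0), lasso (glmnet), and four self-contained learners — bagged
CART forest, gradient-boosted shallow trees, ε-insensitive RBF kernel SVR
by subgradient descent, and a one-hidden-layer tanh MLP (Adam) — under
repeated nested cross-validation: an inner grid search selects
hyperparameters per outer fold, and no model is ever scored on rows its
inner selection saw (asserted by index bookkeeping). The deployed model is
**ridge by declared policy** (interpretability and stability at n ≈ 84),
refit on all rows at the modal inner-selected penalty, even when a tree
ensemble posts a higher CV R²; both numbers are reported. The
"XGBoost"/"gradient boosting" distinction is collapsed into the single
boosted-trees slot. The published protocol is 5×10 nested CV; tests and
the acceptance script scale repeats and grids down to desk size, which
changes runtime, not semantics.

Shapley attribution is exact for linear models
(`φ_ij = β_j (x_ij − mean_ref x_j)`, base = prediction at reference means;
local accuracy to machine precision) and permutation-sampling otherwise,
with interventional marginalization against a reference sample (the
training rows). Each sampled permutation is averaged over `n_ref` (default
10) reference draws — a variance-reduction choice needed to reach ~0.02
agreement with exhaustive coalition enumeration at n_perm in the low
thousands. Dependence "nonlinearity" is summarized by the Pearson r (and
r²) between a feature and its attribution, because that is the scale on
which such plots are conventionally annotated.

## 5. The synthetic world

The generator is a *stated world*, fixed before any acceptance run. Two
subtypes mix with weights 43/84 and 41/84. Published per-cluster profiles
supply age, LVEF, PSD (means 56/41 ms, SD 8), GLS, LVMI, RWT, SBP, DBP,
sex and comorbidity prevalences; eGFR and BNP are log-normal with the
published medians and log-SDs backed out of the published IQRs (medians
are reported with IQRs precisely because these labs are right-skewed). BMI
(27/25 ± 4), LAVI (42/38 ± 10) and E/e′ (16/14 ± 4) are **package
choices** — clinically plausible values documented here, not published
numbers, because the source table omits them. LVEF is truncated at 50
(the HFpEF inclusion criterion), PSD at 0, GWE clipped to [0, 100], and
RD is forced equal to 1(eGFR < 60) for internal coherence.

The mediation path acts on latent z-scales: `z_M = a·z_X + ε_M`,
`z_Y = c′·z_X + b·z_M + γ·z_M² + δ·z_X·z_M + ε_Y`, mapped affinely to
clinical units (GWE uses negated paths — efficiency moves opposite to
waste). When noise SDs are unspecified they are solved so the latent
mediator and outcome have unit variance in the linear case, making a, b,
c′ *standardized* path coefficients that the analysis can recover
directly. The ground-truth indirect effect in the nonlinear case is
defined by the same average-shift construction the analysis uses (cohort
mean of the model-implied outcome change when M moves from its value at X
to its value at X+1 SD), so total = direct + indirect holds exactly by
telescoping in every case.

What a green test does *not* establish: the generator draws each variable
block independently given cluster membership (no residual correlation
between, say, LVMI and SBP beyond what clusters induce), missingness is
token-level and completely at random, and repeat readings have purely
Gaussian, bias-free noise. Real cohorts violate all three; green tests
certify the *estimators*, not the clinical conclusions. Two quantitative
caveats discovered and kept: (i) with a log-normal exposure such as BNP,
the linear analysis on the raw scale recovers an attenuated path (the
planted relation is linear in log-BNP) — parameter-recovery checks
therefore use a Gaussian-exposure world, while detection checks happily
use BNP; (ii) pooling both subtypes confounds the paths with
between-cluster location shifts, so exact recovery is only expected
within a homogeneous (sub)population — which is precisely the argument
for per-subtype mediation.

## 6. Reliability

ICC form is fixed to ICC(2,1) — two-way random effects, absolute
agreement, single measurement — the standard choice when two
interchangeable sonographers re-read the same loops; the source protocol
names no form, so this is documented to make the tests exact. It is
computed from the two-way ANOVA mean squares with the McGraw–Wong
confidence interval (Satterthwaite df). The default replicate noise,
1.14 ms, is the variance-components solution of ICC = σ_b²/(σ_b² + σ_e²)
at ICC 0.98 and between-patient SD 8 ms. Bland–Altman reports
bias ± 1.96·sd (n−1) of the differences, with per-pair (mean, difference)
coordinates for plotting.

## 7. Numerical choices and degenerate inputs

- z-scores use the sample (n−1) SD throughout (so the 2-point column
  {2, 4} standardizes to ±1/√2, not ±1 as the population-SD convention of
  e.g. scikit-learn's scaler would give); medians of even counts are the
  mean of the central order statistics.
- Zero-variance columns: hard error naming the column (z-scoring),
  flagged-and-skipped (group comparison), undefined-and-flagged (ICC with
  zero between-subject variance, dependence profile of a constant
  feature).
- Rank-deficient regression designs error with the collinear columns
  named; inside the bootstrap they count as failed replicates instead.
- All randomness flows from explicit integer seeds; the pipeline derives
  per-stage streams from one master seed (multiplicative hash, kept below
  2³¹), so a re-run is byte-identical.
- XLSX files are read (first worksheet; dates/strings in numeric columns
  become dirty tokens) but artifacts are written as CSV/JSON only — the
  supported R stack provides no XLSX writer, and plain text is the more
  reproducible interchange format anyway.

## 8. Known limitations

Mediation here is a regression decomposition, not a causal identification
strategy: no sensitivity analysis for unmeasured confounding, single
mediator, cross-sectional. The SVR and MLP learners are deliberately
minimal implementations adequate for suite comparison, not
production-grade solvers. The whole-cohort-cluster vs. complete-case-
cluster question (the source is ambiguous about whether subtyping used
150 or 84 patients) is left to the caller: cluster-then-filter and
filter-then-cluster are both expressible and neither is declared
canonical.
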