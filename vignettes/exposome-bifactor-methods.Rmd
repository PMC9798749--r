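---
title: "Modeling the exposome: mixed-type correlations, iterated target rotation, and bifactor scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the exposome: mixed-type correlations, iterated target rotation, and bifactor scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Developmental cohorts measure the environment a child grows up in with
hundreds of variables of mixed format: continuous census composites, ordinal
parent- and youth-report scales, binary exposure indicators. Treating each
variable separately invites multiplicity and ignores that adversities
cluster. `expofactor` condenses such a panel into a single general
("exposome") factor plus a small set of orthogonal domain subfactors, then
quantifies how those factor scores relate to health outcomes. The same
machinery configured for ordinal-only symptom items yields a general
psychopathology factor, so both sides of an exposome–mental-health analysis
can be scored with one toolchain.

The pipeline is: mixed-type correlation matrix → iterative redundancy
reduction → exploratory factor analysis with iterated target rotation →
quasi-confirmatory bifactor model → orthogonal factor scores → association
models. Every stage is driven by a seeded configuration and writes auditable
artifacts.

## The measurement model

Each observed item $y_i$ is a manifestation of a latent normal response
$y_i^*$,

$$y_i^* = \lambda_{g,i}\, g + \lambda_{s,i}\, s_{a(i)} + \sqrt{\psi_i}\,\varepsilon_i,
\qquad \psi_i = 1 - \lambda_{g,i}^2 - \lambda_{s,i}^2,$$

where $g$ is the general factor, $s_{a(i)}$ the one specific factor item $i$
is assigned to, and all factors are mutually orthogonal standard normals.
Continuous items observe $y_i^*$ directly; ordinal and binary items observe
the category into which $y_i^*$ falls relative to thresholds $\tau$. This
latent-response convention is what makes polychoric and polyserial
correlations the natural input to the factor analysis: they estimate the
correlations among the $y^*$, not among the coarsened observations.

## Mixed-type correlations

`mixed_correlation_matrix()` dispatches per pair on declared measurement
levels: Pearson (continuous–continuous), polyserial (continuous–ordinal),
polychoric (ordinal/binary–ordinal/binary). Estimation is two-step maximum
likelihood: thresholds from the univariate margins by inverse-normal
transformation of cumulative proportions, then the correlation maximizing
the bivariate-normal likelihood with thresholds held fixed. Two-step ML is
the standard practice trade-off — it is far faster than joint ML and its
loss of efficiency is negligible at cohort sample sizes.

Numerical choices worth knowing:

* Bivariate-normal rectangle probabilities use a deterministic hybrid
  quadrature (Gauss–Legendre on the arc-sine representation for
  $|\rho| < 0.925$, a singularity-subtracted transformation above), accurate
  to well below $10^{-10}$ — orders of magnitude tighter than the $10^{-7}$
  the estimates need.
* The correlation search is bounded to $(-0.999, 0.999)$; a boundary
  solution (perfect association) is returned clipped with a warning.
* Empty categories are merged with their neighbour, with a warning.
* Pairs use pairwise-complete observations. Pairwise deletion can produce an
  indefinite matrix; `nearest_psd()` restores positive semidefiniteness by
  eigenvalue clipping (floor $10^{-6}$) followed by rescaling to unit
  diagonal. PSD inputs pass through untouched, so smoothing is idempotent.
* A pair with fewer than 10 complete observations is an error, not a guess.

## Redundancy reduction

Real exposure panels contain near-duplicates (the same construct reported
twice) and inert variables. `reduce_redundancy()` replaces the judgment
calls of manual curation with an explicit rule-based loop: per pass it
(1) estimates the mixed correlation matrix, (2) runs a minres EFA at the
parallel-analysis factor count for communalities, (3) collapses groups with
pairwise $|r| \ge 0.90$ to their highest-communality representative (keeping
the original measurement level; a mean-of-standardized composite is
available for continuous-only groups), and (4) drops variables with
communality below $0.10$; it stops when a pass takes no action, or after 9
passes. Each removal is a row in an audit table, so
$|\text{initial}| = |\text{surviving}| + |\text{audited removals}|$ always
holds. The defaults (0.90, 0.10, 9) are deliberately conservative: the merge
threshold only collapses variables that are statistically interchangeable,
and the communality floor only removes variables the factor space cannot
see at all.

## EFA, oblimin, and iterated target rotation

Extraction is minres: uniquenesses minimizing the sum of squared
off-diagonal residuals of $R - \Lambda\Lambda'$, with loadings from the
leading eigenvectors of the reduced matrix. The factor count comes from
Horn's parallel analysis (95th percentile of 100 seeded resamples) unless
overridden. Oblique rotation is direct oblimin ($\gamma = 0$, i.e.
quartimin) by gradient projection, with seeded random orthonormal starts to
avoid rotation local minima; outputs are canonicalized (columns ordered by
sum of squared loadings, leading sign non-negative) so solutions are unique
and reproducible.

Simple-structure rotations penalize cross-loadings even when the data
genuinely contain them. Iterated target rotation (ITR) addresses this:
starting from the oblimin pattern, cells with $|\lambda| < 0.30$ are
targeted at zero, an oblique target rotation is fitted, the target is
rebuilt from the new pattern, and the loop continues until the zero pattern
reproduces itself (typically 1–3 iterations). If the pattern cycles, the
visited solution with the lowest target criterion is returned with a
warning. The 0.30 cutoff matches the conventional salience threshold used
when reading factor tables.

One boundary behaviour is worth documenting: a true cross-loading whose
*initial oblimin estimate* falls below the cutoff is zero-targeted and stays
suppressed — ITR frees cross-loadings the starting pattern reveals, it does
not rediscover those the start hides. In our planted-recovery studies we
therefore use cross-loadings of 0.40–0.45, comfortably above the cutoff;
at exactly 0.35 (with an oblimin estimate of ~0.30) recovery depends on
which side of the threshold the initial estimate lands.

## Bifactor model, fit, and indices

The EFA pattern is converted to a quasi-confirmatory bifactor specification:
each item is assigned to the specific factor of its largest absolute
pattern loading (ties to the lower index, logged), items with no loading
$\ge 0.30$ are excluded (logged), and every item loads on the general
factor. Fitting minimizes the unweighted least-squares discrepancy

$$F = \textstyle\sum_{i<j} \left(r_{ij} - \lambda_{g,i}\lambda_{g,j}
  - \mathbb{1}[a(i)=a(j)]\,\lambda_{s,i}\lambda_{s,j}\right)^2$$

by seeded multi-start L-BFGS-B with analytic gradients. ULS on the mixed
correlation matrix replaces the mean-and-variance-adjusted weighted
estimator used with commercial SEM software: the population solutions are
identical, no asymptotic covariance matrix of the polychorics is needed,
and the fit-index formulas below remain well-defined. It is an
approximation — printed CFI/RMSEA values from weighted estimators are not
numerically comparable. Clustering by family affects standard errors, not
point estimates, so it is out of scope for the point estimator; the
association module's mixed models provide the clustering-aware sensitivity
analysis instead.

Items whose specific loading is below 0.30 are pruned and the model is
refitted until stable, never letting a specific factor fall below 3 items
(the identification floor; pruning freezes there with a warning).

Fit uses the chi-square analogue $T = (N-1)F_{\min}$ with
$df = p(p-1)/2 - 2p$ and an independence baseline:

* $\mathrm{RMSEA} = \sqrt{\max(T - df, 0)/(df\,(N-1))}$
* $\mathrm{CFI} = 1 - \max(T - df, 0)/\max(T_b - df_b,\, T - df,\, 0)$
* $\mathrm{SRMR} = \sqrt{\mathrm{mean}_{i<j}(r_{ij} - \hat\sigma_{ij})^2}$

Reliability and score quality are summarized by explained common variance
$\mathrm{ECV} = \sum\lambda_g^2 / (\sum\lambda_g^2 + \sum\lambda_s^2)$,
omega-hierarchical
$\omega_H = (\sum\lambda_g)^2/\left((\sum\lambda_g)^2 +
\sum_s(\sum_{i\in s}\lambda_s)^2 + \sum\psi\right)$ (with the per-subfactor
analogue $\omega_{HS}$), and factor determinacy
$FD_f = \sqrt{[\Lambda' R^{-1}\Lambda]_{ff}}$.

## Factor scores — and why they are not exactly orthogonal

Scores use the regression method, $\hat F = X R^{-1}\Lambda$, on
listwise-complete standardized rows. Ordinal items are standardized through
conditional-normal scores (the mean of a standard normal truncated to the
category's threshold interval), keeping scoring consistent with the
polychoric measurement model. Determinacy is attached per column; at
$n = 20{,}000$ the empirical correlation between the estimated and true
general factor matches $FD$ to within a few parts in a thousand.

Although the *factors* are orthogonal by construction, regression-method
*score estimates* of orthogonal factors are correlated: their population
correlation matrix is the normalized $\Lambda' R^{-1}\Lambda$, whose
off-diagonals are ~0.15–0.18 for models of the size considered here and do
not vanish as loadings strengthen. This is a structural property of the
estimator, not an implementation artifact; the test suite asserts that the
empirical score correlations match this model-implied matrix rather than
pretending they are zero. Users who need strictly uncorrelated columns
should be aware that any post-hoc orthogonalization trades away score
validity.

## Association models

* `standardized_linear_model()` — OLS with all continuous variables
  z-scored (indicator covariates left 0/1), so coefficients are
  standardized betas; listwise deletion; adjusted $R^2$.
* `delta_r2()` — base (covariate-only) vs full model on the same rows;
  reports both adjusted $R^2$, their difference, and ratio.
* `logistic_model()` — ML logistic fit, OR per SD, Wald 95% CI; suspected
  separation is an error rather than a silently diverging estimate.
* `group_contrast()` — Welch $t$-test (the unequal-variance default is a
  deliberate choice; equal variances are not assumed), classic pooled-SD
  Cohen's $d$, Bonferroni adjustment with family size 7 (the number of
  demographic contrasts run per factor).
* `cluster_random_intercept_model()` — REML linear mixed model with site
  and family random intercepts (via `lme4`), the sensitivity analysis for
  clustered sampling.

Deletion policy is deliberately split: correlations use pairwise-complete
observations (maximizing information for each pair), association models use
listwise deletion (one analysis sample per model, reported as `n`).

## What the synthetic cohorts emulate — and what they do not

`default_cohort_spec()` generates cohorts with the structure the analysis
assumes: a planted bifactor model (general loadings 0.45–0.60, specific
0.40–0.55, formats cycling continuous / 4-category ordinal / 3-category
ordinal / binary), exchangeable family clustering injected as a shared
family component with variance `icc_family` (default 0.30) on every latent
score, MCAR missingness (default 2%), demographic covariates, an income
indicator obtained by thresholding a liability correlated 0.5 with the
general factor, a continuous outcome with planted standardized effects
(defaults: general 0.285, covariates contributing adjusted $R^2 \approx
0.04$, full model $\approx 0.38$), and binary outcomes with a planted odds
ratio (default 1.41) at realistic prevalences (16.7% and 6.5%).

Category counts per ordinal item (2–5) are configurable, not estimated from
any cohort. The generator does *not* emulate: measurement non-invariance
across sites or groups, MNAR missingness, skewed continuous composites,
site-level effects beyond the optional second cluster label, or the
item-specific content of real exposure panels. Passing recovery tests on
these cohorts therefore demonstrates the *estimators* are correct under the
assumed measurement model, not that real exposure data satisfy that model.

## Problem sizes and numerical conventions

The validation studies use sizes chosen to make Monte-Carlo error small
relative to the tolerance being asserted while keeping a full run
comfortable on a laptop: 36 ordinal items at $n = 4000$ for bifactor
recovery (loading RMSE ≈ 0.02 against a 0.05 band), $n = 20{,}000$ for
determinacy calibration (gap < 0.001 against a 0.03 band), $n = 10{,}000$
for association recovery, 50 random tables for the polychoric
grid-likelihood cross-check, and the end-to-end pipeline at $n = 3000$ with
40 items. Determinism is enforced throughout: every stochastic stage
derives a child seed from the master seed and a stage label, numeric CSV
artifacts are rounded to 6 decimals so content hashes are stable, and
reports exclude wall-clock times from hashed content.

Degenerate inputs have defined behaviour rather than undefined results:
zero-margin categories merge, Heywood items are capped (communality 0.995)
with a warning, saturated models ($df \le 0$) error, an empty retained
factor set errors, rotation non-convergence errors with its criterion
trajectory, and pruning never empties a model.

## Known limitations

* ULS fit indices are not numerically comparable to those from weighted
  ordinal SEM estimators; use them for relative judgments within this
  toolchain.
* No asymptotic covariance of the polychoric matrix is computed, so no
  robust standard errors for loadings; the cluster bootstrap across
  families is the intended route when loading SEs matter.
* ITR's recovery of a cross-loading depends on its initial oblimin estimate
  clearing the target cutoff (see above).
* The redundancy-reduction loop is a reproducible stand-in for expert
  curation, not a reconstruction of any cohort's actual curation history.
* Multiple imputation, survey weights, measurement invariance and causal
  inference are out of scope.
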