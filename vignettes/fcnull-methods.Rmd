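---
title: "Null-model benchmarking of structure-function prediction: models, calibration and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Null-model benchmarking of structure-function prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(fcnull)
```

## Why a null-model benchmark

Individual-level prediction of functional connectivity (FC) from structural
connectivity (SC) is usually reported as a correlation between predicted and
empirical FC edge vectors. That number is uninterpretable without two
references that require no model at all:

1. the **training group-average FC** (avgFC), which correlates with any
   held-out subject's FC at roughly the square root of the mean
   inter-subject FC similarity, and
2. the **noisy group average** (navgFC), avgFC plus subject-independent
   Gaussian edge noise, which additionally mimics the *spread* of
   inter-individual variation in model predictions while containing no
   individual information.

If a model's per-subject accuracy and its inter-prediction variability are
both matched by navgFC, its headline numbers demonstrate nothing about
individual-level structure-function coupling. `fcnull` implements these
nulls, the statistics used to compare predictors against them, and the
control analyses (cognition prediction with SC regressed out, network error
maps, centrality reproduction) in one tested pipeline.

## The predictors

With a k-fold assignment (default k = 10, seeded shuffle then contiguous
blocks, remainder spread one per fold), every subject is predicted exactly
once, by a construction that never touches that subject's data:

* **avgFC** — elementwise mean eFC of the k − 1 training folds.
* **navgFC** — avgFC plus a symmetric noise matrix per validation subject:
  i.i.d. `N(0, sigma^2)` on the upper triangle, mirrored, diagonal kept at 1.
  `sigma` is in FC correlation units; 0.1 is the value that reproduces the
  performance regime of published deep-learning predictors on cohorts whose
  inter-subject FC similarity centres on 0.7. Predictions are deliberately
  *not* clipped to [−1, 1] (clipping would distort the tuned noise
  distribution); a `clip` flag exists for users who need bounded values.
  `tune_sigma()` bisects on sigma against the mean per-subject correlation;
  targets above the zero-noise ceiling raise an error (the "glass ceiling").
* **MLP** — a feed-forward reference model mapping Gaussian-resampled SC
  edge vectors to eFC edge vectors with the loss
  `(1 − gamma)(1 − mean_i r(pred_i, target_i)) + gamma * mean_{i<j} r(pred_i, pred_j) + lambda * mean(W^2)`.
  The first term rewards accuracy, the second penalizes collapse onto a
  shared (group-average-like) prediction, the third is weight decay. The
  published reference architecture is 10 hidden layers of 1024 units,
  `gamma = 0.4`, `lambda = 0.01`, 20000 epochs; the exact published loss is
  not restated in the literature we reconstruct, so this two-parameter
  surrogate matches the stated *intent* and is a pluggable component
  (`mlp_loss`) rather than a claim of bit-faithfulness. Optimizer choices
  that the source leaves open are fixed conventionally: ReLU activations,
  He initialization, Adam at 1e-3, full batch. Analytic gradients of the
  correlation terms are verified against finite differences in the tests.
  Desk-scale defaults (width 256, 2000 epochs) train in minutes on one CPU;
  the reference values are available through `mlp_config()`.

## Evaluation statistics

All edge-level statistics operate on the canonical edge vector: the
row-major upper triangle, diagonal excluded, so each edge counts once.
Negative FC edges are included as-is (their treatment is not specified in
the conventions we follow; excluding them is a user-level filter).

* `per_subject_correlation` — Pearson r between predicted and empirical
  edge vectors, one value per subject; constant predictions are flagged NA.
* `concatenated_r2` — squared Pearson correlation of the concatenation over
  subjects; note it is sign-blind (a perfectly anticorrelated prediction
  also scores 1), which the report surfaces rather than hides. The two
  conventions (mean per-subject r vs concatenated R²) are *not* comparable:
  a mean per-subject r of 0.84 coexists with a concatenated R² near 0.56
  because between-subject mean structure inflates neither statistic the
  same way. The package reports both and converts with `r2_to_r()`.
* `preservation_correlation` — across subject pairs i < j, the correlation
  between inter-eFC similarity and inter-prediction similarity. Predictors
  whose per-subject noise is independent score 0 in expectation (navgFC:
  exactly 0 on average); the zero-noise avgFC gives identical predictions
  within a fold and is returned as a flagged NA rather than a number.
* `network_error_map` — per subject and parcel, the correlation between the
  parcel's predicted and empirical FC rows (diagonal entry excluded),
  converted to `ln(1 − r)` and averaged within Yeo-7 networks, then over
  subjects. The natural logarithm is used because it reproduces the
  magnitude range of published network-error tables (e.g. r ≈ 0.81 maps to
  −1.66; a base-10 log would not); r is clipped at 1 − 1e-9 so perfect
  predictions stay finite.

## Centrality reproduction

FC matrices are thresholded at an edgewise significance level
`alpha = 1e-4` on the correlation coefficient: the critical r inverts the
two-sided t test with `T − 2` degrees of freedom (T = 1200 gives
r_crit ≈ 0.112); sub-threshold and surviving *negative* edges are zeroed
(negative-edge interpretability is disputed). Whether the original
procedure was one- or two-sided, and what effective T it used, is not
stated; both are configurable. Degree centrality is computed on the
binarized graph (following the convention of the work that introduced the
threshold), eigenvector and PageRank centrality on the weighted positive
graph — both choices sit behind flags. PageRank uses damping 0.85
(conventional; unstated in the source) and sums to 1 before rescaling.
Centralities are z-scored across the concatenation of all subjects' node
values and mapped linearly onto [−1, 1] per measure — one reading of the
ambiguous "z-scored and rescaled" phrase; the composition is
order-preserving. `centrality_variance_explained` then reports, per
measure, the squared correlation between individual node centralities and
the training-fold average centralities under the usual 10-fold scheme.

## Cognition battery

`run_cognition_battery` predicts a scalar cognition score from ten feature
sets — eFC, SC, pFC, rpFC (pFC reassigned among subjects by a seeded
derangement: never a fixed point, multiset preserved), navgFC, avgFC, and
`\SC` residual variants of the last four — with lasso in 10-fold CV,
repeated over outer loops with re-randomized folds. The penalty is chosen by
nested cross-validation on the training folds only (`cv.glmnet`,
`lambda.min`; the source is silent on penalty selection). Regressing out SC
is per subject across edges (OLS residual of the subject's FC edge vector
on their SC edge vector; residuals are exactly orthogonal to the centered
SC), matching the stated motive of removing each individual's FC~SC linear
dependence.

**Significance convention.** Concatenated out-of-fold CV predictions are
negatively correlated with the outcome under the null: each fold's
prediction leans on the training folds' mean, which anticorrelates with the
held-out values on the order of −1/(k − 1). Measured on 200 null
replicates, the two-sided Pearson test on such predictions rejects far too
often — and almost exclusively with *negative* r, i.e. it detects the CV
artefact, not predictive skill. Because the battery's question is
directional ("can this predictor predict cognition"), each loop reports
both the two-sided p and a one-sided p for positive association, and the
battery's significance call uses the one-sided p, which is close to
nominal (slightly conservative) under the null. No multiple-testing
correction is applied across the ten variants — mirroring the side-by-side
reporting convention — but the family size is annotated in the output.
Constant feature designs (the avgFC variant is identical within a fold)
fall back to intercept-only predictions and cannot become significant.

## The synthetic cohort generator

The generator exists so that every pipeline stage is testable without
access-controlled human data. It matches the *second-order statistics* the
analyses consume, nothing more.

Each subject's latent FC target is the correlation-matrix projection of

```
M_i = w * G + (1 - w) * D_i + nu * S^{1/2} (N_i - I) S^{1/2}
```

where `G` is a shared group template and `D_i`, `N_i` subject-specific
random factor correlation matrices (10 and 5 factors by default), and `S`
scales the extra deviation per Yeo-7 network. Gaussian time series of
length `T` are drawn from each target (Cholesky) and eFC computed as
pairwise Pearson correlation — so FC matrices are automatically valid
(symmetric, unit diagonal, PSD) and within-subject estimation noise is
controlled by `T`, which also gives the centrality threshold a well-defined
sampling distribution. The projection first clips negative eigenvalues and
renormalizes; the Higham alternating projection is applied only if the fast
clip leaves meaningful indefiniteness.

* **Calibration.** The weight `w` is set by bisection so the realized mean
  pairwise inter-subject eFC correlation of a 10-subject pilot batch lands
  within 0.005 of `rho_target` (default 0.70, the regime observed for
  DK-style parcellations at T ≈ 1000). Pilot latents and noise draws are
  reused across bisection iterations, so the calibration objective is
  deterministic and monotone. Infeasible targets (e.g. `rho_target = 1`
  with nonzero deviations) raise an error suggesting a parameter change.
  The emergent consequence — mean per-subject correlation with the training
  average ≈ `sqrt(0.70)` ≈ 0.84 — is a *prediction* of the exchangeable
  factor structure, not a fitted quantity; the acceptance suite verifies it
  emerges. For a 200-parcel Schaefer-like regime the published group-average
  performance (~0.76) implies inter-eFC ≈ 0.577; that value is an inference
  (the source prints inter-eFC for the DK regime only) and is not a preset
  default — pass `rho_target = 0.577` explicitly.
* **Network deviation scales.** Defaults
  `LSN 2.5 > FPN = DMN 1.5 > VAN = DAN 1.0 > VN = SMN 0.6` (multiplier
  `nu = 0.15`) mirror the reported ordering of group-average prediction
  errors across networks: limbic hardest, visual/somatomotor easiest. The
  acceptance suite checks the error ordering *emerges* from these scales
  under the avgFC predictor.
* **SC.** `SC_i = round(exp(a * rankscore(c * g + (1 - c) * d_i) + b + noise))`
  with `a = 1.5`, `b = 3`, noise sd 0.2 and coupling `c = 0.5`: symmetric
  nonnegative integer counts spanning several orders of magnitude (as raw
  streamline counts do), sharing individual structure with FC through
  `d_i`. Rank-based Gaussian resampling (below) is applied per subject for
  the analyses.
* **Cognition.** `y_i = beta . x_i + N(0, 0.5)`, with `x_i` the subject's
  standardized values on 3 seeded SC edges (Gaussian-resampled
  representation) and equal weights `1/sqrt(3)`. The effect is deliberately
  sparse and strong: at the simulated cohort sizes (n = 100–200) the lasso
  detection threshold `~ sqrt(2 log m / n)` for m ≈ 2278 edge features is
  around 0.3–0.4, so a realistic-at-n=1000 diffuse weak effect would be
  undetectable *by construction* at desk scale and would test nothing. The
  chosen effect gives cross-validated SC-to-cognition correlations around
  0.8–0.9 at n = 100 (band pre-registered by simulation before the test
  suite was frozen); `cognition_beta = 0` yields the global null used by
  the type-I checks.

**What the generator does not emulate** — hemodynamics, temporal
autocorrelation, spatial geometry of parcels, scanner/session effects,
non-Gaussian FC tails, realistic SC sparsity (zeros are rare at the default
log-scale) and any causal SC-to-FC mechanism. Passing tests therefore show
the *pipeline* behaves correctly under controlled second-order structure;
they are not evidence about real neuroimaging data.

## Gaussian resampling of SC

One standard-normal draw per upper-triangle edge; draws sorted and assigned
smallest-to-smallest so rank order is preserved; tied counts receive the
mean of the Gaussian order statistics their tie group spans (deterministic
given the draws, keeps tied edges equal — the source is silent on ties);
mirrored to the lower triangle; finally affinely rescaled so the
off-diagonal mean and sd are 0.5 and 0.1 *exactly* (standardize, then map),
rather than relying on the sample moments of the draws — making the
0.5/0.1 contract bit-testable. The diagonal stays 0 and is excluded from
the moments (inclusion or exclusion is unstated in the source; exclusion is
the convention here). Constant off-diagonal input raises an error (the sd
rescale is undefined).

## Problem sizes and reproducibility

All simulation scales are package choices, stated here: calibration,
preservation and performance checks run on n = 100 subjects, p = 68
parcels, T = 1000 (50 independent cohorts for the Monte-Carlo preservation
mean); the cognition battery runs on n = 200 (so the weakest arm,
navgFC\SC, sits above the lasso detection threshold) with a
3-layer × 64-unit, 100-epoch reference network and 5 outer loops; the
type-I check uses 200 null replicates at n = 50 with 60 features. Every
stochastic function takes an explicit seed and restores the caller's RNG
state; cohorts are deterministic given their config.

## Known limitations

* The MLP loss is a surrogate for an unpublished functional form; swap in
  the original via the pluggable loss if it becomes available.
* Matrix I/O is plain TSV plus a JSON manifest; no binary container is
  shipped, so very large cohorts are better regenerated than stored.
* The preservation correlation is undefined for exactly-identical
  predictions (returned as flagged NA) — callers must handle the sentinel.
* Concatenated R² is sign-blind; never report it without the per-subject
  distribution.
* The cognition battery's significance calls are uncorrected across the
  ten-variant family, by design; treat borderline p-values accordingly.
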