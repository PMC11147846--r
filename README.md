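# fcnull

Null-model benchmarking for individual-level prediction of functional
connectivity (FC) from structural connectivity (SC) in the human connectome.

## The problem

A string of studies report machine-learning models that predict an
individual's resting-state FC matrix from their white-matter SC matrix,
quoting individual-level correlations of 0.55–0.78 on Human Connectome
Project data. Those numbers are hard to interpret in isolation, because the
**group-average FC is itself an excellent predictor of any individual's FC**:
with inter-subject FC similarity `rho ~ 0.7`, the training-set average
correlates about `sqrt(rho) ~ 0.84` with each held-out subject (Desikan-
Killiany-style parcellation; ~0.76 for a 200-parcel Schaefer-style one).
Worse, adding subject-independent Gaussian noise to the group average
(**navgFC**) mimics both the reported prediction performance *and* the
reported inter-individual variability of model predictions — while carrying
no individual information whatsoever.

`fcnull` packages the two null predictors, the evaluation statistics needed
to judge any SC-to-FC model against them, and the control analyses that probe
whether predicted FC carries individual-level information:

* **avgFC** — cross-validated training group-average predictor (the "glass
  ceiling"): prediction for every validation subject is the mean eFC of the
  training folds.
* **navgFC** — `avgFC + E`, with `E` symmetric i.i.d. `N(0, sigma^2)` edge
  noise drawn independently per subject (default `sigma = 0.1`), plus
  `tune_sigma()` to match any weaker predictor's performance.
* **Evaluation** — per-subject edge-vector correlations under 10-fold CV;
  concatenated variance explained (`R^2`); the *preservation correlation*
  (across subject pairs, `cor(inter-eFC, inter-prediction)` — 0 for navgFC
  by construction); per-parcel/Yeo-7 network error maps (`ln(1 - r)`).
* **Reference model** — a feed-forward network mapping SC edge vectors to FC
  edge vectors with the variance-preserving loss
  `(1 - gamma) * (1 - mean within-subject r) + gamma * (mean between-subject r) + lambda * mean(W^2)`.
* **Centrality reproduction** — degree / eigenvector / PageRank centralities
  on FC thresholded at edgewise `p = 1e-4`, and the variance in individual
  centralities explained by training-average centralities.
* **Cognition battery** — lasso prediction of a cognition score from ten
  predictor variants (eFC, SC, pFC, rpFC, navgFC, avgFC and their `\SC`
  residuals with the subject's own SC regressed out), exposing that the
  predictive power of `pFC\SC`-style analyses enters through the regressed-out
  SC, not the predictions.
* **Synthetic cohorts** — a calibrated generator of coupled time
  series / FC / SC / cognition with controllable inter-subject similarity,
  heavy-tailed streamline counts and network-dependent deviation variance, so
  every stage is testable without access-controlled neuroimaging data.
* **SC normalization** — rank-based Gaussian resampling of streamline counts
  to off-diagonal mean 0.5 / sd 0.1, exactly.

## Worked example

```r
library(fcnull)

coh   <- generate_cohort(cohort_config(n_subjects = 40, t_len = 400, seed = 42))
folds <- make_folds(coh$n, 5, seed = 1)

fit <- fit_fc_predictor(coh, "navg", folds, sigma = 0.1)
summary(fit, coh)
#> <fc_evaluation> predictor 'navg'
#>   per-subject r: mean 0.728 (sd 0.011), quartiles 0.724 / 0.729 / 0.735
#>   concatenated R^2: 0.530
#>   preservation r: -0.004
#>   network errors ln(1-r):
#>     VN    SMN    DAN    VAN    LSN    FPN    DMN
#> -1.426 -1.354 -1.346 -1.357 -1.228 -1.313 -1.278

avg <- fit_fc_predictor(coh, "avg", folds)
mean(per_subject_correlation(avg, coh))
#> 0.831

tune_sigma(coh, folds, target = 0.55, seed = 2)
#> 0.213
```

Reading: the noisy group average predicts each subject's FC at `r ~ 0.73`
even though its per-subject noise is pure fabrication; its preservation
correlation is ~0 (it destroys the geometry of individual differences); the
noise level can be tuned to hit any target below the 0.83 group-average
ceiling. The limbic network (LSN) shows the largest error (least negative
`ln(1 - r)`), the visual/somatomotor networks the smallest — the ordering
reported for group-average predictions on real data.

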