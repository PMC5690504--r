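---
title: "Ranking external-marker placement for respiratory-motion surrogacy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking external-marker placement for respiratory-motion surrogacy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During thoracic radiotherapy the tumour region moves with respiration.
Skin markers are the routine surrogate: their motion, captured optically
at tens of hertz, is mapped to the internal target position for
pre-treatment setup and intra-treatment gating or tracking. Placement is
commonly chosen by eye. This package treats placement as a measurable
property: given time-synchronized traces of nine candidate sites (a 3x3
thoracic/abdominal grid, rows "upper" M1-M3, "middle" M4-M6, "lower"
M7-M9) and of one internal reference point, score each site, select a
subset, and quantify what that subset buys in prediction error.

## The pipeline

```{r, eval = FALSE}
library(respmark)
sessions <- simulate_sessions(seed = 1)
sel <- select_markers(aggregate_scores(score_all(sessions, "cca")))
report <- compare_modes(sessions, config = train_config(seed = 1))
```

Four stages, each exposed as ordinary functions:

1. **Scoring.** `cca_first_correlation()` computes the first canonical
   correlation between the marker's (AP, SI) channels and the reference's
   (AP, SI) channels: covariance blocks are whitened by a symmetric
   inverse square root and the largest singular value of the whitened
   cross-covariance is returned. `pca_score()` instead collapses each
   trace to its first principal component (`stats::prcomp` on
   mean-centred, unscaled channels - all channels share millimetres, so
   no standardization) and correlates the two mono-dimensional signals.
2. **Aggregation and selection.** Scores are averaged per marker across
   sessions with a population SD. `select_markers()` admits a marker iff
   `mean >= tau_corr` and `SD <= tau_sd`.
3. **Correlation model.** `fit_setup_model()` trains one Sugeno
   neuro-fuzzy model per output axis on the pooled selected-marker
   signals.
4. **Evaluation.** `compare_modes()` fits six marker subsets
   (CCA-selected, PCA-selected, all nine, and the three fixed regions)
   and reports held-out RMSE per axis; `importance_degree()` turns
   ascending RMSE into a region ranking.

## Selection thresholds

The selection idea - high correlation coefficient together with minimum
standard deviation - is qualitative in the source methodology; no
numeric thresholds are published. We formalize it as the conjunction
`mean >= 0.95` and `SD <= 0.25`. These are the loosest round values that
reproduce the published four-patient outcome exactly: with the reported
per-marker aggregates (0.98 +/- 0.18, 0.67 +/- 0.23, 0.97 +/- 0.20,
0.97 +/- 0.32, 0.67 +/- 0.21, 0.96 +/- 0.30, 0.98 +/- 0.21,
0.67 +/- 0.21, 0.97 +/- 0.19 for M1..M9) they admit M1, M3, M7, M9,
reject M4 and M6 on the SD ceiling despite passing means, and reject M2,
M5, M8 on the mean. Both thresholds are inclusive; the separate coverage
gate (`coverage_check()`, "more than 90%") is strict, because it is
phrased as a strict exceedance. The coverage rule is a data-quality
diagnostic, not the selector: it flags markers whose PC1 compresses the
channels poorly, and is left configurable rather than wired into
`select_markers()`.

A note on plausibility: a mean of 0.97 with SD 0.32 cannot arise from
values bounded in [0, 1] (the maximum SD at that mean is about 0.17).
The published aggregates are nevertheless used verbatim as inputs when
testing the selection rule, since only their ordering relative to the
thresholds matters there.

## The neuro-fuzzy model

Rule `j` has Gaussian premises in every input dimension and a linear
consequent. Firing strength is the product t-norm
`w_j(x) = prod_k exp(-(x_k - c_jk)^2 / (2 sigma_jk^2))`; the output is
the firing-strength-weighted average of the consequents. (A Sugeno
weighted-average system of this form never exercises the OR/implication/
aggregation operators of the classical fuzzy pipeline - probabilistic OR
and sum aggregation are no-ops here, which is why they are not
parameters.)

* **Initialization.** Fuzzy c-means (`fcm_cluster()`, written in-package:
  alternating exact center/membership updates, objective recorded after
  each center update so monotone non-increase is guaranteed) clusters the
  input columns; premise centers are the cluster centers and widths the
  membership-weighted SDs (floored at 1e-6 to survive constant columns).
  Consequents start from one global least-squares fit.
* **Hybrid training.** Per epoch: (i) all consequents are re-solved
  exactly by least squares on firing-strength-weighted regressors - the
  previous consequents remain feasible, so training RMSE cannot increase
  at this step; (ii) one gradient step on centers and widths. A premise
  step that raises RMSE by more than 10% is rejected and retried with a
  halved learning rate (at most 8 halvings per epoch; the reduction
  persists). Widths are floored at 1e-6. If a singular consequent system
  appears, it is ridge-regularized (`1e-8 x` mean Gram diagonal) with a
  warning.
* **Degenerate inputs.** If every rule's firing strength underflows
  (below 1e-300), prediction falls back to the nearest rule's consequent
  and the samples are flagged.

Defaults: 3 rules, fuzzifier 2, 50 epochs, premise learning rate 0.01,
70/30 train/test fraction. None of these is published for the original
study; they are implementation choices. Three rules suffice because the
simulated marker-to-target mapping is close to linear; the rule count is
the knob to raise for strongly hysteretic data. One model per output axis
(AP, SI) is fitted - the standard practice for correlation models - and
the input vector is the sample-wise concatenation of the selected
markers' AP and SI channels, with no temporal lags: the traces are
synchronized, and lag modelling is out of scope.

The train/test split is contiguous (first 70% of samples) rather than
random: respiratory traces are strongly serially correlated, and a random
split would leak near-duplicate samples into the test block. Across
sessions, evaluation holds out the last ~30% of whole sessions instead,
which is the honest analogue at session granularity.

## What the simulator emulates

`simulate_session()` builds every trace from one shared breathing
waveform, `w(t) = sin^(2k)(pi t / T)` with `k = 2` by default - a
standard asymmetric-breathing surrogate with value 0 at end-exhale
(cycle start) and 1 at end-inhale, chosen because the phantom software
the method was developed on does not publish its internal waveform. A
marker's AP channel is `jitter x ap_gain x 10 x ap_expansion_cm x
w(t - phase_lag) + drift_rate x t + noise`; SI likewise from the
diaphragm amplitude. Five default cycles span 0.5-1.3 cm chest-wall
expansion, 1.2-2.2 cm diaphragm motion and 4-6 s periods, sampled at
25 ms for 60 s.

The default marker presets state the world the evaluation assumes:

* **M1, M3, M7, M9 (border):** gains ~0.9, noise 0.6 mm, gain jitter
  0.08 - target correlation 0.97-0.99, stable across sessions.
* **M4, M6 (mid-lobe):** largest gains (1.05-1.10) but noise 1.8 mm and
  strong lognormal session-gain jitter (SD 1.5 on the log scale) - high
  amplitude, inconsistent coupling, so their cross-session score spread
  is large.
* **M2, M5, M8 (midline - sternum line, xiphoid, navel):** low gains
  (~0.3), 0.3-0.4 s phase lag, noise 1.5-1.6 mm - target correlation
  0.6-0.7.
* **Reference:** SI-dominant (gain 0.85) with small AP component and
  0.3 mm noise, mimicking a diaphragm-adjacent internal landmark.

Amplitudes, lags and noise levels are in the ranges reported for
optically tracked chest markers; the published per-patient
amplitude/frequency table is in unstated device units (amplitudes
2200-3100, "frequencies" 73-77) and is deliberately not reproduced
numerically - only its ordinal content (border/mid-lobe amplitude exceeds
midline) informs the presets. What a green end-to-end test establishes is
therefore structural: *given* a world where border sites couple tightly
and consistently to the target, the CCA and PCA pipelines find them and
the RMSE ranking rewards them. It does not validate the presets against
patients; real data adds baseline drift regimes, hysteresis between
inhale and exhale, cough/irregular-breathing outliers and
marker-occlusion gaps that this generator does not model.

Session-to-session variability is a single lognormal gain multiplier per
marker per session (median 1), applied to both axes - a crude but
standard stand-in for day-to-day marker repositioning and posture change.
Noise draws are consumed from the RNG stream even when a spec sets
`noise_sd = 0`, so changing one marker's parameters never perturbs
another marker's realization under the same seed.

## Numerical choices and degenerate cases

* CCA clamps the returned correlation to [0, 1]; constant channels raise
  a degenerate-input error; a rank-deficient covariance block (e.g. a
  noiseless marker whose AP and SI are exactly collinear) engages a
  documented ridge (`1e-8 x` mean diagonal) with a warning.
* PC1 sign is fixed by positive correlation with the largest-variance
  channel, making reflection of a channel (e.g. an SI axis recorded
  upside down) score-invariant.
* `pca_reduce()` accepts down to 3 samples so that the textbook
  degenerate configurations (collinear points, symmetric 4-point cross)
  are computable; practical use has hundreds of samples.
* FCM restarts (new random memberships, at most 5 times) when centers
  collapse; points landing exactly on a center get a crisp membership
  row.
* Ranking ties (identical subsets) are broken lexicographically by
  subset name, so reports are deterministic.
* All randomness flows from one master seed through
  `derive_seed(master, stage_label)` (a small string-hash mixer below
  2^31), so any stage can be re-run independently and reproducibly.

## Known limitations

* The simulator's stationarity (fixed cycle per session, no intra-session
  amplitude drift beyond linear baseline drift) flatters all correlation
  estimates; absolute RMSE values are not transferable to patients.
* Scores are aggregated per session and selection is performed on
  training sessions only inside `compare_modes()`; with few sessions the
  SD estimate is coarse, and mid-lobe markers occasionally slip through
  in a single world - the end-to-end claims are therefore majority
  statements over many seeds, not per-seed guarantees.
* "RMSE(selected) comparable to RMSE(all markers)" is operationalized as
  `RMSE(selected) <= 1.25 x RMSE(all)`: the substantive claim is that
  selection loses nothing relative to feeding every marker to the model,
  and in this world selection usually wins outright because the mid-lobe
  markers' unstable gains degrade the all-marker model on held-out
  sessions.
* The CLI and CSV schemas are deliberately minimal; there is no DICOM or
  4D-CT ingestion, no geometry, no dose - placement ranking only.
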