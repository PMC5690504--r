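# respmark

Where should skin markers go? In external beam radiotherapy of thoracic
tumours, reflective markers on the chest and abdomen are the standard
surrogate for internal target motion during patient setup and respiratory
gating. Their placement is usually chosen empirically by the operator, yet
different sites track the internal target very differently. `respmark`
ranks the nine sites of a uniform thoracic marker layout (M1–M3 upper,
M4–M6 middle, M7–M9 lower row) by how well each site's motion predicts an
internal reference trajectory, and quantifies the payoff of informed
placement with a neuro-fuzzy correlation model.

## Method

For each candidate marker the package records time-synchronized
anterior–posterior (AP) and superior–inferior (SI) displacement traces
together with the internal reference point's trace (the left–right axis is
negligible for respiratory motion and is dropped). Two input-selection
scores are computed per marker and session:

* **CCA score** — the first canonical correlation
  `rho_1 = max_{a,b} cor(X a, Y b)` between the marker's channel set
  `X = (AP, SI)` and the reference's channel set `Y = (AP, SI)`;
* **PCA score** — `|cor(PC1(X), PC1(Y))|`, the absolute correlation of the
  two first principal-component signals, with the marker's PC1
  explained-variance fraction `lambda_1 / sum(lambda_i)` kept as a
  data-quality figure (a ">90% coverage" gate is available via
  `coverage_check()`).

Scores are aggregated across sessions into mean ± SD, and a marker is
**selected** when `mean >= 0.95` and `SD <= 0.25` — high correlation with
minimum variability. The selected markers feed a Sugeno-type adaptive
neuro-fuzzy inference system (ANFIS): Gaussian premise membership
functions seeded by fuzzy c-means clustering, product t-norm firing
strengths

`w_j(x) = prod_k exp(-(x_k - c_jk)^2 / (2 sigma_jk^2))`,

linear rule consequents, weighted-average defuzzification
`y = sum_j w_j (a_j' x + b_j) / sum_j w_j`, and hybrid training (exact
least squares for the consequents, gradient descent for the premises).
One model per output axis predicts the reference AP and SI displacement.
Prediction quality is measured by `RMSE = sqrt(mean((A_i - P_i)^2))` on
held-out sessions, and regions are ranked by ascending RMSE — the
"importance degree" of each placement region.

Because clinical 4D phantom/patient data are not distributable, the
package ships a parametric breathing simulator (`simulate_sessions()`):
a raised-sine-power waveform `sin^(2k)(pi t / T)` scaled by chest-wall
and diaphragm amplitudes, with per-marker gain, phase lag, drift, noise
and session-to-session gain jitter. Default presets emulate the reported
structure: border sites track tightly, midline sites weakly, mid-lobe
sites strongly but inconsistently.

## Worked example

```r
library(respmark)

sessions <- simulate_sessions(seed = 1)          # five 60 s sessions
agg <- aggregate_scores(score_all(sessions, "cca"))
select_markers(agg)$selected
#> [1] "M1" "M3" "M7" "M9"

report <- compare_modes(sessions, config = train_config(seed = 42))
report
```

A seed-1 run prints (RMSE in mm on held-out sessions):

```
           mode axis   rmse_mm n_markers rank
1  selected_cca   ap 0.3277757         4    1
2  selected_cca   si 0.6530632         4    1
3  selected_pca   ap 0.3277757         4    2
4  selected_pca   si 0.6530632         4    2
5   all_markers   ap 1.2829211         9    5
6   all_markers   si 1.9422491         9    5
7         upper   ap 0.3833411         3    4
8         upper   si 1.0358325         3    4
9        middle   ap 2.6618504         3    6
10       middle   si 5.9795392         3    6
11        lower   ap 0.3967579         3    3
12        lower   si 0.7585244         3    3
```

Both selection algorithms pick the four border markers; a model built on
them predicts the internal trajectory to ~0.3 mm (AP) / ~0.7 mm (SI),
about as well as using all nine markers and an order of magnitude better
than the middle region alone — border regions dominate, midline sites add
little.

The same pipeline is available from the shell:

```sh
exec/respmark run --out run1 --seed 1
```

## Acceptance script

`scripts/acceptance.R` re-runs the complete pipeline (simulation →
CCA/PCA scoring → selection → ANFIS training → six-mode RMSE report)
against the installed package from a single seed and writes a JSON
results file:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
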