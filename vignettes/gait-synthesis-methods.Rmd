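---
title: "Methods: margin-of-stability kinematics and constraint-based gait synthesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: margin-of-stability kinematics and constraint-based gait synthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitsynth)
```

## The problem

Dynamic balance during walking is commonly quantified by the *margin of
stability* (MoS): how far the body's (extrapolated) centre of mass sits
from the edge of the base of support. In frail populations — here,
older adults filmed walking with an ordinary smartphone — collecting
enough data to train predictive models of MoS is hard, which motivates
a synthetic-data route: fit a generator to a small gait table, generate
a statistically faithful synthetic table that preserves the
biomechanical dependencies, and check whether a regressor trained only
on synthetic rows predicts real MoS as well as (or better than) one
trained on the real rows.

`gaitsynth` implements that whole loop: 2D pose-landmark kinematics,
signal preprocessing, a constraint-validated Gaussian-copula
time-series synthesizer, fidelity scoring, and the TRTR/TSTR utility
comparison with SHAP attribution. A fixture generator emulating the
statistical structure of a 14-participant older-adult cohort makes the
pipeline exercisable without any recorded data.

## Kinematic model

The input is a MediaPipe-Pose-style sequence of 33 2D landmarks per
frame. Per frame:

1. **Segment centres of mass.** Each segment's CoM is the unweighted
   mean of its landmark positions. The segment partition is: head =
   face landmarks 0–4; torso = shoulders and hips (11, 12, 23, 24);
   each arm = elbow + wrist (13/15, 14/16); each leg = knee + ankle
   (25/27, 26/28). The landmark set is fixed by the calculation needs;
   the partition into segments is this package's choice consistent with
   that set.
2. **Whole-body CoM.** Weighted mean of segment CoMs with standard
   anthropometric mass fractions — head 8.1%, torso 49.7%, arms 2.65%
   each, legs 16.1% each. The fractions sum to 0.953, not 1; the
   weighted mean divides by their sum, so this is exactly as harmless
   as it looks and is implemented as printed.
3. **CoM velocity.** Backward difference scaled by the frame rate,
   `v(t) = f·(CoM(t) − CoM(t−1))`. The first frame's velocity is
   undefined; it copies the second frame's so all series keep the same
   length.
4. **Extrapolated CoM.** `XCoM = CoM + v/ω₀` with the inverted-pendulum
   eigenfrequency `ω₀ = √(g/l)`. The pendulum length `l` is a
   configurable fraction (default 1.0) of the mean CoM-to-ankle-midpoint
   distance; the fraction is configurable because only "a fraction" is
   specified by the upstream method.
5. **Margin of stability.** The base-of-support boundary is the
   infinite line through the two ankle landmarks;
   `MoS = min(d_XCoM, d_CoM)` where both are perpendicular point-to-line
   distances `|cross_z(v_point, v_boundary)|/‖v_boundary‖`. No clamping
   to the ankle segment is applied. This is an *unsigned* margin — the
   min of two non-negative distances — even though some of the
   literature defines MoS as signed; we implement the computational
   definition used to produce the data this package emulates.
6. **Step width.** Euclidean distance between the two ankle landmarks.

**Units and calibration.** Internal units are metres throughout.
Landmark files are stored as read (normalized image coordinates);
conversion to metres happens in the kinematics stage, either with an
explicit metres-per-unit factor or with "auto-height" calibration:
scale = participant height / median landmark-0-to-ankle-midpoint span
over the first 30 valid frames. The nose (landmark 0) is a head-top
proxy, so auto-height is biased a few percent high; the calibration
test budgets for this.

**A known tension.** With metric coordinates and the position-based
distance above, a standing adult's CoM is ~0.9 m from the ankle line in
the frontal plane, so landmark-derived MoS values are decimetre-scale.
The 0.004–0.054 m MoS band that the table-level fixture reproduces (and
that the synthesizer's bound preservation is tested against) cannot
arise from this formula at metric scale; the upstream results are also
internally inconsistent about MoS units (bounds printed in metres,
prediction errors of ~3.5 suggesting millimetres). We keep the formula
as defined, enforce the printed band in the table-level fixture where
it is a marginal-distribution constraint, and flag the unit question as
unresolved rather than silently rescaling.

## Preprocessing

* **Filtering.** Fourth-order Butterworth low-pass at 4 Hz (standard in
  gait analysis: locomotor signal lives below ~4 Hz at 30 fps), applied
  forward-backward so the phase response cancels. The implementation
  pads each series with an odd-symmetric reflection (6× the effective
  filter order) and demeans before filtering, so constant signals pass
  through unchanged and edge transients fall on the padding. Filtering
  is applied per landmark coordinate *before* metrics are recomputed.
* **Imputation.** Gaps (lost tracking) are filled with the mean of the
  nearest preceding and following observations; edge gaps copy the
  nearest observation. Observed values are never altered.
* **Missing-data gate.** A window whose missing-frame fraction strictly
  exceeds 20% is rejected. Since no gait-event segmentation is
  available, "one gait cycle" is approximated by a 30-frame (1 s)
  window — a typical stride time for slow older-adult walking.
* **Outliers.** Per sequential variable, values outside μ ± kσ with
  k = 2 (population σ) are removed; on Gaussian data this retains
  ≈95.4%. Statistics are computed *per participant* — pooling would
  conflate between-subject level differences with within-subject
  noise — and a row is dropped if any of its sequential variables is
  flagged. Whether the original analysis pooled or stratified is
  unstated; stratification is the defensible choice.
* **Scaling.** Min–max to [0, 1], fitted on the training split only and
  applied to test data (fitting on everything would leak the test
  range). In TSTR the scaler is fitted on the synthetic training table.

## The synthesizer

The generator the upstream study used is a closed vendor tool; only its
metadata configuration, bounds and constraint behaviour are specified.
The re-specified generator here is an explicit, inspectable model:

* **Marginals** — the empirical quantile function of each training
  column (interpolated, quantile type 8). This captures skewness and
  bounded support without parametric assumptions.
* **Cross-column dependence** — a Gaussian copula over normal scores
  `z = Φ⁻¹((rank − ½)/n)`, so rank correlations survive the monotone
  marginal transforms (Spearman ρ of the copula relates to its Pearson
  parameter by ρ_S = (6/π)·asin(r/2)).
* **Temporal structure** — per-column lag-1 autoregression estimated
  within entities. The innovation correlation is adjusted by
  `(1 − φ_a φ_b)/(s_a s_b)` so the *stationary* cross-correlation of
  the AR(1) latents matches the training copula; if the adjustment
  leaves the matrix indefinite it is repaired to the nearest PSD
  correlation matrix with a warning.
* **Entity structure** — correlated participant-level offsets with
  per-column between-entity standard deviations, estimated from the
  entity means of the normal scores.
* **Sampling contract** — the synthetic table has the training table's
  exact shape: same entities, per-entity row counts, and timestamp
  grids (copied, hence a KS complement of exactly 1.0 on Timestamp).
  Static categorical attributes are assigned by stratified proportional
  allocation — each synthetic entity takes its training counterpart's
  Age/BMI/fall-history combination — so categorical frequencies are
  preserved exactly. Numeric draws are clamped to the metadata bounds
  (the bounded-generation contract); since empirical quantiles cannot
  leave the training range, clamping is a safety net rather than an
  active mechanism.
* **Constraints** — validate-and-resample: draw, compute Spearman ρ for
  each constrained pair, and accept only when every strict threshold
  (Step_Width–MoS ρ > 0.7; CoM_Velocity–MoS ρ < −0.3) holds, advancing
  a deterministic seed sequence. This mirrors the "custom validation
  function" framing rather than constrained optimization, and makes
  every accepted table satisfy the constraints by construction.

## Fidelity scoring

Per-column scores are the KS complement (numeric, including the
timestamp) and TV complement (categorical); *column shapes* is their
unweighted mean. *Pair trends* scores numeric pairs by
`1 − |ρ_real − ρ_syn|/2` (Pearson) and pairs involving a categorical by
the total-variation similarity of normalized joint contingency tables,
with numeric partners discretized into pooled quartile bins; these
formulas follow the common synthetic-data-evaluation convention, since
only the framework, not the formulas, is specified upstream. *Overall
fidelity* is the arithmetic mean of the two aggregates. Hellinger
distances use 30 equal-width bins on the pooled range (no binning rule
is specified upstream; the bin count is a parameter and is reported
with the scores), and the overall Hellinger value is the mean over
columns (the alternative — pooled binning — is not what per-variable
reporting suggests).

## Utility evaluation

The regressor is gradient-boosted trees (squared-error objective,
histogram method, single-threaded for reproducibility) over the seven
Table-style inputs (CoM x/y, CoM velocity, step width, Age, BMI, fall
history), target MoS. Hyperparameters are chosen by exhaustive grid
search — `n_estimators {100, 200, 300} × max_depth {3, 5, 7} ×
learning_rate {0.01, 0.1, 0.2} × subsample {0.8, 1.0} ×
colsample_bytree {0.8, 1.0}`, i.e. 108 combinations (the upstream text
says "135 (3 × 3 × 3 × 2 × 2)", but that product is 108; the full
printed Cartesian product is what is implemented) — with 5-fold
cross-validation minimizing MAE, ties to the first combination.

TRTR: random row-level 70:30 split, scaler fitted on the train split,
evaluation on the held-out rows. TSTR: train on all synthetic rows
(scaler fitted on them), evaluate on the *complete* real table. TRTR
and TSTR run independent searches (whether the original shared
hyperparameters is unstated). Row-level splitting follows the upstream
description; note it allows temporal adjacency between train and test
rows of the same participant, so TRTR is an optimistic baseline —
participant-level splitting can be done by the caller via the exposed
split utilities. Metrics are MAE, MSE, RMSE = √MSE and R² = 1 − SSE/SST
(undefined and flagged for a zero-variance target). SHAP attributions
come from the tree-path-dependent TreeSHAP of the fitted booster; the
suite checks local accuracy (base + contributions = prediction) row by
row. Comparison reports `Δ = TSTR − TRTR` and `|Δ|/TRTR × 100` per
metric and per-feature SHAP changes with direction.

## The fixture generator

The fixture emulates the *statistical shape* of the study cohort, not
its physiology:

* 14 participants, 1,878 total rows (even split, remainder to the
  first participant), 30 fps, per-entity timestamps restarting at 0 and
  stepping by 1/30 s. (The upstream timestamp range 0.0–7.2594 is
  mutually inconsistent with 30 fps × ~134 rows per participant; the
  uniform 1/fps grid is used and the inconsistency left alone.)
* Cohort anthropometrics from truncated normals at 86.7 ± 6.2 y,
  1.656 ± 0.099 m, 64.0 ± 12.5 kg; fall history Bernoulli(0.3).
* Sequential variables from the same copula family the synthesizer
  uses: latent AR(1) (φ = 0.6) plus correlated entity offsets
  (τ = 0.35), with the latent correlation set from the target Spearman
  values 0.768 (step width–MoS) and −0.487 (velocity–MoS) through
  ρ_S = (6/π)·asin(r/2); a step width–velocity Spearman of −0.30 keeps
  the matrix positive definite. Marginals are scaled Beta shapes inside
  the study bounds (step width right-skewed).
* Fall history shifts the MoS latent down by 0.3 SD, giving the
  evaluation stage a risk-factor signal to find; the size is a fixture
  parameter, not an upstream claim, chosen small enough to dilute the
  pooled step width–MoS Spearman by under 0.01.
* The landmark-level fixture is a sinusoidal toy walker (cadence
  1.6 Hz, 3 cm sway, oscillating ankle separation spanning the step
  width band, 0.002 image-unit landmark noise, 2% dropout). It
  exercises the kinematics and preprocessing chain end to end; it does
  *not* reproduce the table-level rank-dependence structure, so
  constraint validation against the study thresholds applies to the
  table-level fixture.

**What passing fixtures shows — and does not.** Green tests show the
pipeline's operations are correct on data with the declared moments,
bounds and dependencies. They do not show that real MediaPipe output is
this clean: real pose sequences have autocorrelated tracking error,
occlusion bursts, camera distortion and genuine gait variability that
the fixtures deliberately idealize.

## Numerical and design choices

* Problem sizes: unit tests run the fixture at 6 × 60 rows; copula
  recovery checks use 10,000 rows; distributional checks 100,000 draws.
  The full default study (1,878 rows, single-combination grids in
  tests) runs in seconds.
* Seeds are explicit everywhere (`fixture`, `fit`, `sample`, `split`,
  `train` in the pipeline config); sampling retries advance `seed + k`.
  Same seeds ⇒ bit-identical artifacts.
* Degenerate inputs: constant series filter to themselves and remove no
  outliers (σ = 0); constant features min-max to 0 with a warning;
  constant columns fail rank constraints with an explicit reason rather
  than NA propagation; coincident ankles are an error (undefined base
  of support); an all-missing series cannot be imputed and errors.
* Ages below 75 and BMI above 30 fall outside the two defined category
  bins; they map to the nearest bin (0 and 1 respectively) with a
  warning rather than erroring, since simulated cohorts legitimately
  produce them.
* Tie-breaks: grid search takes the first minimizer in grid order;
  ranks use average ties.

## Limitations

Sagittal-plane stability, gait-event detection and centre-of-pressure
dynamics are out of scope. The synthesizer reproduces lag-1 temporal
structure only — longer-range stride-to-stride correlations (e.g.
fractal variability) are not modelled. The MoS unit question above is
inherited, not resolved. TRTR/TSTR results on fixtures quantify the
harness, not clinical performance.
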