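# gaitsynth

Margin-of-stability gait analysis from 2D pose landmarks, and
constraint-preserving synthetic gait time series with fidelity and
utility benchmarking.

## Who this is for

Movement scientists and ML practitioners working with markerless
(MediaPipe-Pose-style) gait recordings of older adults, where datasets
are small and synthetic augmentation must respect biomechanics. The
package covers the full loop: landmark kinematics → preprocessing →
copula-based synthesis with rank-correlation constraints → resemblance
scoring → train-on-synthetic-test-on-real (TSTR) evaluation with SHAP
attribution.

## The model in brief

From 33 2D landmarks per frame, the whole-body centre of mass is the
segment-weighted mean

    CoM = Σ w_j · CoM_j / Σ w_j     (head 0.081, torso 0.497, arms 0.0265, legs 0.161)

with per-frame velocity `v(t) = f·(CoM(t) − CoM(t−1))` at frame rate
`f`. The extrapolated centre of mass adds velocity scaled by the
inverted-pendulum eigenfrequency,

    XCoM = CoM + v/ω₀ ,   ω₀ = √(g/l) ,

and the margin of stability is the minimum perpendicular distance of
XCoM and CoM from the base-of-support boundary — the line through the
two ankle landmarks:

    MoS = min(d_XCoM, d_CoM) ,   d_P = |cross_z(P − a, b − a)| / ‖b − a‖ .

Step width is the ankle-to-ankle Euclidean distance.

The synthesizer is a Gaussian copula over normal scores with empirical
quantile marginals, per-column lag-1 autoregressive coupling and
entity-level offsets; sampling copies the training timestamp grids and
entity shapes, clamps numeric draws to the learned bounds, and
validates Spearman rank constraints (Step_Width–MoS ρ > 0.7,
CoM_Velocity–MoS ρ < −0.3) by deterministic resampling. Fidelity is
scored by KS/TV complements, pairwise trend preservation and Hellinger
distances; utility by TRTR vs TSTR gradient-boosted regression (MAE,
MSE, RMSE, R²) with TreeSHAP attribution. See the methods vignette
(`vignettes/gait-synthesis-methods.Rmd`) for assumptions, parameter
choices and limitations.

## Worked example

Fit the synthesizer to the built-in 14-participant fixture cohort
(1,878 timesteps), generate a constraint-validated synthetic table, and
score it:

```r
library(gaitsynth)

real      <- simulate_gait_table(fixture_spec(), seed = 11)
model     <- fit_synthesizer(real, derive_metadata(real), seed = 12)
synthetic <- generate_validated(model, gait_constraints(), seed = 13)
attr(synthetic, "constraint_report")
#> <constraint_report> overall: PASS
#>              a   b cmp  rho   observed satisfied reason
#> 1   Step_Width MoS   >  0.7  0.7630897      TRUE
#> 2 CoM_Velocity MoS   < -0.3 -0.4935674      TRUE

fidelity_report(real, synthetic)
#> <fidelity_report> shapes 0.9735 | pair trends 0.9597 | overall 0.9666
#>   Hellinger overall 0.0356 (30 bins)
#>            column       metric     score
#>         Timestamp KSComplement 1.0000000
#>  X_Coordinate_CoM KSComplement 0.9728435
#>  Y_Coordinate_CoM KSComplement 0.9771033
#>      CoM_Velocity KSComplement 0.8791267
#>        Step_Width KSComplement 0.9861555
#>               MoS KSComplement 0.9462194
#>               Age TVComplement 1.0000000
#>               BMI TVComplement 1.0000000
#>      Fall_History TVComplement 1.0000000
```

The synthetic table keeps the biomechanical rank structure (both
constraints hold), reproduces the timestamp grid exactly
(KS complement 1.0), preserves categorical frequencies exactly
(TV complement 1.0), and stays inside the learned bounds. Utility:

```r
grid <- model_grid(n_estimators = c(100, 200), max_depth = c(3, 5),
                   learning_rate = 0.1, subsample = 1, colsample_bytree = 1)
run_trtr(real, grid, seed = 14)
#> <evaluation_report> TRTR (train 1315 / test 563)
#>   MAE 0.0050 | MSE 0.0000 | RMSE 0.0062 | R2 0.6622
run_tstr(synthetic, real, grid, seed = 14)
#> <evaluation_report> TSTR (train 1878 / test 1878)
#>   MAE 0.0049 | MSE 0.0000 | RMSE 0.0062 | R2 0.6470
```

On this fixture the synthetic-trained model matches the real-trained
baseline (R² 0.65 vs 0.66, MAE slightly lower): the generator carries
essentially all of the fixture's learnable signal into the synthetic
rows. `compare_reports(trtr, tstr)` tabulates per-metric deltas,
percent changes and per-feature SHAP shifts. The full pipeline
(fixture → preprocess → synthesize → score → evaluate → compare, with
all artifacts and a provenance log) is one call:

```r
res <- run_study(study_config(), out_dir = "study_out")
```

A thin CLI over the same functions ships in
`inst/scripts/gaitsynth.R` (subcommands `simulate`, `synth`,
`fidelity`, `run`).

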