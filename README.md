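# pdmotor

Analysis tools for smartphone-administered Parkinson's disease (PD) motor
assessments. The package targets researchers developing digital biomarkers
from an eleven-task phone battery — single/alternating/target finger
tapping, circle and spiral tracing, free circle drawing, bimanual
mirror-trail coordination, rest and postural tremor recordings, foot
tapping and a 3 m out-and-back gait test — where the phone records
time-stamped touch positions and 3-axis accelerometer + Euler-angle
streams.

The package implements the complete chain:

1. **Synthetic cohorts** (`simulate_cohort()`): raw per-task sensor
   streams for PD patients and healthy controls (HC), driven by a single
   latent severity *s* ∈ [0, 1] with monotone effect structure — slower
   and noisier tapping with within-session fatigue drift, 4–6 Hz tremor
   with amplitude ∝ *s* in tremor-dominant patients, shrinking drawn radii
   (micrographia), lagging right-hand coordination, slowed gait. Clinical
   labels derive from severity: MDS-UPDRS Part III score
   `round(clip(68·s + ε, 0, 68))`, Hoehn & Yahr (H&Y) stage by monotone
   binning (HC ≡ stage 0).
2. **Feature extraction** (`extract_features()`): the battery's per-task
   feature set — tap counts/valid/missed/paired, summed tap bias,
   interval mean and population variance, tapping-frequency declining
   slope (OLS *r = at + b* on 1 s windows), trail bias, tracing velocity
   and slope, finger-to-centroid distance slope at 3 Hz, drawing angular
   velocity (0.3 s grid), mirrored left–right coordination distance,
   passed trail points, per-axis acceleration/rotation summaries, the
   power-weighted tremor frequency, and peak-based step counts and
   walking velocity.
3. **Classification** (`run_experiment()`): repeated stratified 90/10
   holdout (grid search by inner 5-fold CV on the training split) across
   five model families — linear single-layer network, SVM, ridge logistic
   regression, random forest, gradient boosted trees — under three
   labelling schemes: PD/HC (2 classes), H&Y (6), MDS-UPDRS band (4:
   HC, mild ≤ 32, moderate 33–58, severe ≥ 59). Metrics: accuracy
   N<sub>c</sub>/N<sub>t</sub> and class-count-weighted
   precision/recall/F1, W = Σᵢ wᵢXᵢ / Σᵢ wᵢ.
4. **Importance** (`explain_experiment()`): Shapley-value attributions of
   the best model, g(x′) = φ₀ + Σⱼ φⱼx′ⱼ, by exact subset enumeration
   (M ≤ 12) or antithetic permutation sampling (local accuracy holds
   exactly in both); global importance = mean |φ| per feature, task
   importance = sum over a task's features in the global top 10; plus a
   tapping-task-only ablation (`ablation_experiment()`).

## Worked example

```r
library(pdmotor)

cohort <- simulate_cohort(generator_config(n_pd = 125, n_hc = 75, seed = 1))
feats  <- extract_features(cohort)
exp    <- run_experiment(feats, "pdhc", n_repeats = 20, seed = 1)
exp
#> <pd_experiment scheme=pdhc, 20 repeat(s), 5 model(s)>
#>   linear_nn      accuracy 0.918 (0.051)
#>   logistic       accuracy 0.945 (0.049)
#>   random_forest  accuracy 0.940 (0.050)
#>   svm            accuracy 0.938 (0.052)
#>   xgboost        accuracy 0.952 (0.048)

imp <- explain_experiment(feats, exp, seed = 1)
head(imp$task, 3)
#> # A tibble: 3 × 2
#>    task importance
#>   <int>      <dbl>
#> 1     3     0.41
#> 2     4     0.20
#> 3     2     0.05
```

(Numbers above are from one local run; exact values depend on the seed.)
Read: every model separates simulated patients from controls with ~0.92–0.95
mean holdout accuracy; the tremor recordings (tasks 3–4) dominate the
diagnosis because overt 4–6 Hz tremor is specific to the PD group in the
generator, with the alternating tapping task (task 2) next.
`autoplot(exp)`, `autoplot(imp$global)` and `plot_task_importance(imp$task)`
draw the corresponding figures; `tidy()`/`glance()` return tibbles.

Session streams round-trip through a JSON schema
(`write_session_file()` / `read_session_file()`), so recorded data in the
same schema can replace the simulator everywhere. A thin subcommand CLI
over these functions ships in `inst/cli/pdmotor.R`.

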