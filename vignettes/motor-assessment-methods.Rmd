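---
title: "Methods: simulating and analysing smartphone motor assessments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing smartphone motor assessments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdmotor)
```

## The analysis problem

Parkinson's disease (PD) motor signs — bradykinesia, rest and postural
tremor, micrographia, impaired bimanual coordination, slowed gait — can be
captured remotely by a smartphone battery of eleven short tasks: single and
alternating finger tapping, nose-to-screen target tapping, circle and
spiral tracing, free circle drawing, a two-handed mirror-trail coordination
task, two tremor recordings, foot tapping and a 3 m out-and-back walk.
The phone records two stream types: time-stamped touch samples
(tapping/tracing/drawing/coordination) and 3-axis accelerometer samples
with Euler angles (tremor/foot tapping/gait).

`pdmotor` implements the full analysis chain for such data: per-task
feature extraction, repeated-holdout classification of diagnosis (PD vs
healthy controls), Hoehn & Yahr (H&Y) stage (controls as stage 0, six
classes) and MDS-UPDRS Part III severity band (controls, mild ≤ 32,
moderate 33–58, severe ≥ 59; four classes), and Shapley-value attributions
aggregated into feature- and task-level importance, including an ablation
that reruns the classifiers on the alternating-tapping features alone.

Because raw clinic recordings of this kind are not publicly distributable,
the package includes a first-class synthetic cohort generator. Every
benchmark reported by the package's tests and acceptance script is computed
on cohorts from this generator.

## The synthetic cohort model

A single latent severity $s \in [0,1]$ drives every task. Group-specific
Beta distributions generate $s$ (PD centred mid-scale with a floor of 0.12,
anchored to the observation that a diagnosed PD cohort's motor scores start
around 8 of 68; controls concentrated near zero, reflecting age-related
motor decline). Labels derive from $s$: the MDS-UPDRS III total is
$\mathrm{round}(\mathrm{clip}(68\,s + \varepsilon,\,0,\,68))$ with Gaussian
label noise $\varepsilon$ (SD 4 by default), and the H&Y stage is a fixed
monotone binning of $s$ for PD, stage 0 for controls.

Every derived stream parameter is monotone in $s$:

* **Tapping** is a renewal process with mean interval
  $\mu(s) = \mu_0 (1 + \alpha s)$ ($\mu_0 = 0.35$ s, $\alpha = 0.8$),
  multiplicative interval noise, and a within-session upward interval
  drift proportional to $s$ (fatigue → negative frequency slopes). Tap
  placement noise inflates with $s$; alternation errors (same-side double
  taps) and outside-circle taps occur with probability increasing in $s$.
* **Tremor** adds an $s$-scaled sinusoid, frequency drawn uniformly from
  the classical 4–6 Hz parkinsonian band, to baseline sensor noise, on a
  random 3-D axis and on the Euler angles. Only PD subjects express overt
  tremor, and only a fraction (75% by default) are tremor-dominant — the
  akinetic-rigid minority oscillates at 15% amplitude, controls not at
  all. This mirrors the clinical specificity of rest tremor and keeps the
  diagnosis benchmark non-degenerate.
* **Tracing/drawing** follows the reference trail (or a free circle) at a
  speed reduced by $s$ and decaying within the session; the drawn radius
  shrinks at $\gamma(s)$ points/s (micrographia) and angular velocity
  decays at $\delta(s)$ rad/s².
* **Coordination** traces the left trail cleanly while the right hand
  reproduces the mirrored trajectory delayed by $\tau(s) = 0.4\,s$ seconds
  plus independent noise.
* **Gait and foot tapping** are acceleration peak trains; walking speed is
  $v(s) = 1.2\,(1 - 0.5 s)$ m/s over the fixed 6 m course, cadence and
  foot-tap rate decline with $s$.

Hand-specific tasks are generated per hand with a mild severity asymmetry
(±15%), mirroring the typical lateralisation of PD onset. One root seed
determines the cohort; per-subject child seeds are derived
deterministically, so identical configurations reproduce byte-identical
cohorts.

**What the generator does not emulate.** Real recordings contain device
and grip artefacts, postural drift, pauses, missing sessions, re-starts,
and correlated non-motor covariates; severity in patients is not a scalar.
Passing benchmarks on these cohorts therefore demonstrates that the
pipeline recovers the *designed* effect structure at realistic effect
sizes and sample sizes — not that it attains any particular accuracy on
clinical data.

## Feature extraction

The extractors follow the battery's feature set: per-hand tap counts
(total/valid/missed, paired taps for the alternating task), summed tap
bias to the nearest circle centroid, inter-tap interval mean and
*population* variance, and the tapping-frequency declining slope (1 s
non-overlapping complete windows, OLS of window counts on mid-times);
trail bias (per-sample mean nearest-reference distance — a mean rather
than a sum so the value is invariant to touch sampling rate), average
tracing velocity and its OLS slope, and the slope of the
finger-to-centroid distance series resampled at 3 Hz; drawing angular
velocity mean and slope on a 0.3 s grid after angle unwrapping; mirrored
left–right coordination distance and passed trail points (tolerance 10
points); per-axis acceleration SD/RMS and Euler-angle SDs with the tremor
frequency as the power-weighted mean frequency over 1–12 Hz; and peak-based
foot-tap counts, step counts and walking velocity (6 m divided by the
first-to-last step-peak span).

Numerical choices worth recording:

* **Tremor spectrum.** The spectrum is the sum of per-axis periodograms of
  the mean-removed axes. A rectified magnitude spectrum
  ($|\mathbf{a}|$ of a zero-centred oscillation) doubles the apparent
  frequency, so the per-axis form is the default; the magnitude variant
  remains available via `extraction_config(tremor_spectrum = "magnitude")`
  for streams carrying a gravity offset.
* **Peak prominence.** The adaptive threshold is
  $\max(2\,\mathrm{MAD}, 0.25\,(\max - \mathrm{median}))$ of the
  magnitude. A pure MAD rule admits baseline-noise maxima on quiet
  streams, which inflates the step span and biases gait velocity low; the
  excursion floor suppresses them while leaving genuine steps (an order of
  magnitude above noise) untouched.
* **Paired taps.** Invalid taps are skipped — they neither pair nor reset
  the alternation state — and a pair completes whenever the next valid tap
  lands on the circle opposite the previous unpaired valid tap. This is
  the most permissive rule consistent with "outside the circle or out of
  order does not count", and it equals the maximum adjacent opposite-side
  matching (verified against an exhaustive oracle in the tests).
* **Degenerate inputs.** Fewer than two taps, fewer than two complete
  frequency windows, empty streams, a zero-radius point cloud, or a
  missing hand all yield flagged missing values; the cohort table imputes
  them with the column median and records every imputed cell.
* **Tie-breaks.** OLS fits use the closed-form normal equations; argmax
  ties in classification resolve to the first class level; importance ties
  resolve lexicographically by feature name.

## Classification protocol

Each experiment repeats (100 times by default; the packaged benchmarks use
20 to keep a laptop run in minutes) the following: a stratified 90/10
train/test split (simple random split when any class is a singleton);
per-model grid search by 5-fold cross-validation *on the training portion
only*; refit on the full training split; metrics on the held-out 10%.
Accuracy is $N_c/N_t$; precision, recall and F1 are averaged with weights
equal to per-class test counts, appropriate for the strongly imbalanced
severity classes; undefined per-class ratios count as 0. Means and SDs are
reported over repeats.

Five model families run by default: a single-layer linear network
(multinomial logistic capacity, `nnet::multinom`), SVM (`e1071`), ridge
logistic regression (`glmnet`), random forest (`ranger`), and gradient
boosted trees (`xgboost`). Features are z-scored (training statistics
only) for the linear/SVM/logistic families; tree models consume raw
features. The small published grids live in `default_grids()`.
Cross-validated tuning inside the training split is a deliberate
leakage-free choice. Split sequences depend only on the seed and the
labels, so ablation arms with different feature sets see identical splits.

## Shapley-value importance

Attributions use the additive explanation model
$g(x') = \varphi_0 + \sum_{j=1}^{M} \varphi_j x'_j$ over presence
indicators $x' \in \{0,1\}^M$. Feature "absence" is represented by
substituting the cohort median (the default background). For $M \le 12$
the $\varphi_j$ are computed by exact subset enumeration; beyond that by
antithetic permutation sampling (each sampled permutation paired with its
reverse). Marginal contributions telescope along a permutation, so
$\varphi_0 + \sum_j \varphi_j$ equals the model output *exactly* for every
explained sample under both estimators; for additive models the estimates
equal the closed form $w_j (x_j - b_j)$.

Explanations are computed for the experiment's best model (highest mean
holdout accuracy) refitted on the full cohort — the fitting set for the
explained model is otherwise under-determined, and the full-cohort refit
explains the model one would deploy. Global feature importance is the mean
absolute Shapley value over all explained subjects (summed across classes
for multi-class schemes, whose per-class breakdown is retained); task
importance sums the importances of a task's features that reach the global
top 10. The top-10 restriction prevents a task with many weak features
from outranking a task with a few strong ones, and the effect sizes past
the tenth feature fall off quickly in practice.

## Benchmarks and problem sizes

The packaged checks use: a 200-subject default-effects cohort (125 PD /
75 HC, the clinic ratio scaled up) with 20 holdout repeats for the
diagnosis benchmark; a 100-subject cohort whose severity signal is
confined to the alternating-tapping task (`severity_tasks = 2`) for the
task-importance and ablation checks; and constructed feature tables for
planted-signal recovery. These sizes put Monte-Carlo error around 1–2
accuracy points while keeping the full suite inside a few minutes on one
core.

```{r, eval = FALSE}
cohort <- simulate_cohort(generator_config(n_pd = 125, n_hc = 75, seed = 1))
feats <- extract_features(cohort)
exp <- run_experiment(feats, "pdhc", n_repeats = 20, seed = 1)
glance(exp)
imp <- explain_experiment(feats, exp, seed = 1)
autoplot(imp$global)
```

## Known limitations

* The generator's effect sizes are plausibility-driven design choices, not
  fits to any recorded dataset; no distributional statistics of real
  streams were available to calibrate against.
* A scalar severity with per-task noise cannot produce the dissociations
  real patients show (e.g. tremor-dominant vs gait-dominant progression)
  beyond the tremor-prevalence mixture.
* The H&Y labels derive noiselessly from the latent severity, so stage
  classification on synthetic cohorts is easier relative to score-band
  classification than it would be with clinically rated stages.
* Permutation-sampled Shapley values are exact in their sum but carry
  per-feature sampling error of order $1/\sqrt{n_\mathrm{perm}}$;
  rankings of closely separated features can swap between seeds.
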