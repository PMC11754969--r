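---
title: "Methods: stress-vs-relaxation HRV analysis with hrvstress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stress-vs-relaxation HRV analysis with hrvstress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Acute mental stress shifts cardiac autonomic balance toward sympathetic
dominance: the mean RR interval (RRI) shortens, vagally mediated
high-frequency (HF, 0.15–0.4 Hz) oscillations shrink, and low-frequency (LF,
0.04–0.15 Hz) measures rise relative to relaxation. Heart rate variability
(HRV) therefore supports automated stress detection, but psychiatric
populations — major depressive disorder (MDD) and panic disorder (PD) —
show blunted and altered autonomic reactivity, so a classifier trained to
separate stress from relaxation behaves differently in patients than in
healthy controls (HC). `hrvstress` implements the full analysis chain for a
longitudinal three-group protocol (five visits, each with five consecutive
5-minute phases: rest, mental-arithmetic stress, rest, nature-scene
relaxation, rest): cohort simulation, artifact correction, a 20-feature HRV
battery, two normalisation regimes, subject-wise repeated cross-validated
classification with random forests and multilayer perceptrons, exact tree
Shapley attribution, and within-subject ΔHRV group statistics.

Because raw clinical recordings of this kind are not freely distributable,
the package ships a seeded synthetic-cohort generator as a first-class,
tested module; every downstream stage runs identically on real long-format
RRI tables (`read_rri_table()`).

## The synthetic cohort generator

`simulate_phase_rri()` draws beats iteratively,

\[ t_{k+1} = t_k + RR(t_k)/1000, \qquad
   RR(t) = b + A_{LF}\sin(2\pi f_{LF} t + \varphi) +
           A_{HF}\sin(2\pi f_{HF} t + \psi) + \varepsilon, \]

with \(f_{LF} \approx 0.095\) Hz, \(f_{HF} \approx 0.25\) Hz (small
per-participant jitter) and white beat-to-beat noise \(\varepsilon\).
A two-oscillator model is the simplest generator whose parameters map
one-to-one onto the analysed features: \(A_{LF}, A_{HF}\) control the band
powers and their normalised units, the noise floor controls the entropies,
and \(b\) the mean RRI. Generation stops at the first beat whose cumulative
time exceeds the phase duration, so a nominal 300-s phase sums to 300 s
(+ at most one beat).

Structure of the emulated study (defaults of `cohort_config()`):

* **Group sizes** 41/47/59 (MDD/PD/HC), 5 visits of 5 phases of 300 s.
* **Lower HRV in patients**: multiplicative amplitude shift 0.7 and a −40 ms
  baseline offset for MDD and PD.
* **Stress reactivity** (fractional changes in the stress phase, relative to
  the other phases): mean RRI −8%/−4%/−4% for HC/MDD/PD is paired with HF
  amplitude −35%/−15%/−15% and LF amplitude +35%/+15%/+15%; controls react
  roughly twice as strongly as patients, matching the direction of the
  published group comparisons. One lognormal reactivity multiplier per
  participant (log-SD 0.3) creates between-subject heterogeneity.
* **Between-participant variation**: baseline SD 70 ms; per-band lognormal
  amplitude multipliers (log-SD 0.35).
* **Visit drift**: one additive baseline offset per visit (SD 50 ms by
  default), shared by all five phases of that visit. This operationalises
  "daily states" — day-to-day autonomic level shifts that dwarf the
  within-visit task effect and that motivate personalized longitudinal
  scaling.
* **Missingness**: visit 1 always attended; later visits retained with
  probability 0.884, chosen so that the expected number of retained sessions
  is about 650 of the 735 scheduled. `apply_missingness()` also accepts
  exact per-group retained-session counts (e.g. 181/191/278) when an
  analysis needs the published sample sizes precisely.

What the generator does **not** emulate: respiratory sinus arrhythmia proper
(HF is a fixed-frequency oscillator, not respiration-coupled), circadian
structure beyond the visit offset, ectopy/artifact processes, clinical-scale
trajectories, and medication effects. Tests passing on this cohort therefore
demonstrate the correctness and the qualitative behaviour of the pipeline,
not clinical performance on real recordings.

## The 20-feature battery

`extract_features()` returns, in canonical order: mean RRI (s), SDNN, RMSSD
(ms), pNN50 (%), TRI, TINN (ms); ln-power in VLF/LF/HF bands and their sum
(ln s²), LFnu, HFnu, LF/HF; SD1, SD2 (ms); ApEn, SampEn; DFA α1, α2; and the
correlation dimension. Conventions, stated once and applied everywhere:

* **SD denominator**: sample SD (n−1) for SDNN and all scalers.
* **Artifact rule** (`correct_artifacts()`): beats deviating more than 25%
  from an 11-beat running median are replaced by cubic-spline interpolation
  over beat index; a series with more than 30% flagged beats is rejected.
  This automates the visual editing step used with commercial software.
* **Spectra**: the tachogram is cubic-spline resampled at 4 Hz over
  cumulative beat time, mean-removed, and Welch-averaged with 150-s Hann
  windows at 50% overlap (2–3 segments on a 300-s phase — a deliberate
  variance/VLF-resolution trade-off); band powers are trapezoid integrals of
  the one-sided PSD; absolute powers are natural logs of s² quantities.
  No smoothness-priors detrending is applied before the PSD.
* **Geometric measures**: RRI histogram with the conventional 1/128-s bins;
  TRI = N over the modal bin count; TINN from an exhaustive least-squares
  search of the triangular baseline points on the bin grid (the two sides of
  the triangle separate, so each side is optimised independently; equal-error
  ties resolve to the narrowest triangle).
* **Entropies**: embedding dimension 2, tolerance r = 0.2 × sample SD of the
  analysed segment (the tolerance adapts per series). ApEn includes
  self-matches (Pincus); SampEn excludes them and counts template pairs over
  the first N−m positions. Zero-variance series return 0 by convention; a
  SampEn with zero template matches is reported as `NA` — an undefined
  value, excluded listwise downstream with a logged count — never silently
  substituted.
* **DFA**: non-overlapping boxes at every integer size in 4–16 (α1) and
  17–64 (α2), order-1 detrending per box, tail beats beyond the last full
  box discarded. Note that with this convention the α1 estimator on white
  noise has expectation ≈ 0.58 rather than the asymptotic 0.5 — a known
  small-box bias — with Brownian input landing near 1.5; the test suite
  checks these bands on means over fixed seed blocks.
* **Correlation dimension**: Grassberger–Procaccia with embedding dimension
  10 and delay 1 beat (configurable — no standard exists for 5-minute RRI
  windows, so defaults mirror common HRV software), correlation sums on a
  30-point log-radius grid, slope fitted over the middle third of radii with
  0 < C(r) < 1.
* **Poincaré**: the identity-exact convention SD1² = mean(Δ²)/2 (hence
  SD1 = RMSSD/√2 exactly) and SD2² = 2·SDNN² − SD1². The textbook "SD of
  (x_{k+1}±x_k)/√2" definitions agree with these only up to O(1/n) edge
  effects, so the algebraic identities were made exact and the rest
  documented here.

## Scaling regimes

Two mutually exclusive normalisations:

* **Train z-scaling** (`fit_train_scaler()`/`apply_scaler()`): per-feature
  mean/SD from the training fold only, applied to the fold's test rows.
  Constant features pass through as zero with a warning.
* **Personalized longitudinal scaling** (`longitudinal_scale()`): each
  participant's records — all five phases of all retained visits — are
  z-scored within participant. It is applied **before** any train/test
  split, and the train z-scaler is then not used. This mirrors the published
  design and therefore deliberately uses each participant's full record,
  including sessions that later fall into test folds; the package reproduces
  that property rather than "fixing" it, and this paragraph is the
  documentation of that choice. Participants with fewer than two records are
  dropped (zero-filling would fabricate a class-informative constant).
  The transform is idempotent.

As a QA instrument, `embed_2d()` provides an exact t-SNE (perplexity 50,
5000 gradient-descent iterations by default, early exaggeration 12 for 250
iterations, learning rate 200, seeded initial layout) plus the mean
silhouette width of the task labels in the embedding as a separation score.
On drift-dominated cohorts the silhouette after longitudinal scaling exceeds
the one before.

## Classification design

Rows are (participant, visit, task) feature vectors; stress is the positive
class. Evaluation uses 10-fold cross-validation repeated 20 times.
**Splits are subject-wise**: participants, never rows, are partitioned, so
no individual contributes to both train and test (a runtime guard asserts
this on every fold). Folds are stratified by clinical group with remainders
dealt to the currently smallest folds; task stratification is automatic
because every session contributes one stress and one relaxation row. Each
repeat uses a fresh fold plan (seed = base seed + repeat index); metrics
(accuracy, F1, recall, precision on the stress class, and AUC from the
stress probability) are fold-averaged within repeat and reported as mean ±
SD over repeats, overall and per group. `undersample()` equalises group
sample sizes at the session level so stress/relaxation pairs survive
together; `per_group_models()` trains and tests on one group exclusively.

* **Random forest** (ranger probability forest): tree count tuned over
  {50, 100, 200} by subject-wise 5-fold inner CV on the training rows; other
  hyperparameters remain library defaults (Gini, √p candidate features,
  unlimited depth). Ties resolve to the smallest tree count.
* **MLP** (implemented in the package: no multi-hidden-layer perceptron with
  this interface exists among the available dependencies): dense ReLU layers
  (4,8,16) or (4,8,16,32), sigmoid output, binary cross-entropy with L2
  penalty 1e-4, full-batch Adam at initial learning rates 1e-4/1e-3/1e-2 —
  a 6-point grid searched the same way (ties resolve to the smaller
  architecture, then the smaller rate). Early stopping holds out a
  subject-wise 10% validation slice and stops after 10 consecutive epochs
  without a 1e-4 improvement of the validation score, restoring the best
  weights; the score is the negative validation log-loss, because with
  full-batch training and a small subject-wise slice a quantized accuracy
  score plateaus immediately and would stop training before any learning.
  Maximum 1000 epochs; non-convergence returns the best-so-far model with a
  warning. No dropout.

## Shapley attribution

`tree_shapley()` computes exact path-dependent TreeSHAP attributions of the
predicted stress probability, implemented in C++ against the fitted ranger
trees (split structure from the ensemble; node covers and leaf values
reconstructed by routing the training rows with their inbag multiplicities).
Local accuracy — base value plus attribution sum equals the prediction —
holds to machine precision and is asserted in tests against both the model's
own predictions and a brute-force subset-enumeration Shapley oracle on small
trees. Attributions are computed on test folds only. `aggregate_importance()`
ranks features by the mean **absolute** attribution, averaged first within a
repeat (over all its test rows) and then across repeats; the signed mean is
emitted alongside, since bar-plot conventions differ and ranking by |·|
matches standard importance plots. Ties keep the canonical feature order.
MLP attribution is out of scope (the tree algorithm does not apply).

## ΔHRV statistics

`delta_hrv()` forms stress-minus-relaxation differences per participant-visit
(after scaling, when a scaled regime is analysed — never by scaling the
differences). Sessions missing either task are skipped with a logged count,
and visits are pooled as independent records, a simplification matching the
session-level sample counts of the emulated analysis. `group_anova()` routes
on variance homogeneity, assessed by Brown–Forsythe (median-centred Levene)
at α = 0.05 — the robust default, since the original analysis names no
homogeneity test: homogeneous features get Fisher's one-way ANOVA with
Bonferroni-adjusted pooled-variance pairwise t-tests (adjusted p =
min(1, 3·p)); heterogeneous ones get Welch's ANOVA with Games-Howell
post-hocs (implemented from the standard studentised-range formulas; no
installed package provides them). η² is always reported from the Fisher
sums-of-squares decomposition, even on the Welch route, and pairwise
Cohen's d uses the pooled SD. `reactivity_summary()` emits one row per
feature and assigns a direction label ("HC > MDD, PD") only where the main
effect and the relevant post-hoc comparisons are significant; a significant
main effect with no significant post-hoc yields no label, which is a
legitimate outcome of the routing. No multiple-testing correction is applied
across the 20 features, matching the emulated analysis.

## Numerical and degenerate-input choices

* Constant series: entropies 0, SD1/SD2 0, TRI 1, TINN 0, DFA exponents and
  correlation dimension 0; spectral logs of zero power are non-finite and
  such rows are excluded listwise from models.
* Zero HF power flags LF/HF as `NA` with a warning rather than ±Inf.
* All randomness (simulation, fold plans, model seeds, undersampling, t-SNE
  initial layout) flows from explicit integer seeds; identical configuration
  and seed reproduce bit-identical outputs, which the tests assert.
* Paired t-tests on identical pairs return t = 0, p = 1; a nonzero constant
  difference is flagged degenerate instead of fabricating a statistic.

## Problem sizes used by the tests and the acceptance script

Simulation-backed checks run on reduced cohorts chosen as the package's own
test conditions: the ordering reproduction uses 10/10/13 participants over
4 visits with visit drift SD 150 ms and 5 CV repeats at a fixed 100-tree
forest; the planted-signal attribution check uses 8/8/8 participants over
3 visits. Structural bookkeeping (735 scheduled sessions, 650 retained,
1300 task samples, 362 MDD samples) is always computed at the full published
scale, which costs only seconds because it needs no feature extraction.

## Known limitations

* The oscillator cohort cannot validate clinical effect sizes; only
  directions, orderings and pipeline correctness.
* Path-dependent TreeSHAP explains the model's cover-weighted conditional
  expectations; it is not an interventional attribution.
* The exact t-SNE is O(n²) per iteration and intended for QA-scale inputs
  (up to a few thousand rows).
* ΔHRV ANOVA treats repeated sessions of one participant as independent;
  mixed-effects modelling is out of scope by design.
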