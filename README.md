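# hrvstress

Stress-vs-relaxation analysis of heart rate variability (HRV) in clinical and
healthy populations, as an R package.

Acute mental stress shortens the mean RR interval (RRI), suppresses
high-frequency (HF, 0.15–0.4 Hz) vagal oscillations and raises low-frequency
(LF, 0.04–0.15 Hz) measures relative to relaxation. Patients with major
depressive disorder (MDD) or panic disorder (PD) show blunted autonomic
reactivity compared with healthy controls (HC), which makes automated stress
detection from HRV harder in exactly the populations that would benefit most
from it. `hrvstress` is for researchers in digital psychiatry and
psychophysiology who want a tested, reproducible pipeline for this design:

* a seeded **synthetic cohort generator** for longitudinal three-group
  protocols (five visits × five 5-minute phases: rest, mental-arithmetic
  stress, rest, relaxation, rest), modelling each phase's beats as
  `RR(t) = b + A_LF sin(2π f_LF t + φ) + A_HF sin(2π f_HF t + ψ) + ε`
  with group-specific stress reactivity, between-subject heterogeneity,
  per-visit "daily state" drift and missed visits;
* automated **artifact correction** (running-median flagging, cubic-spline
  replacement) and the standard **20-feature HRV battery**: mean RRI, SDNN,
  RMSSD, pNN50, TRI, TINN; ln VLF/LF/HF/total power (Welch periodogram of
  the 4-Hz spline-resampled tachogram), LFnu, HFnu, LF/HF; Poincaré SD1/SD2;
  ApEn, SampEn (m = 2, r = 0.2·SD); DFA α1 (boxes 4–16), α2 (17–64);
  Grassberger–Procaccia correlation dimension;
* two normalisation regimes — fold-internal **train z-scaling** and
  **personalized longitudinal scaling** (each participant z-scored over all
  of their own sessions and phases) — plus an exact t-SNE with a silhouette
  score as a separation QA;
* **subject-wise, group-stratified 10-fold cross-validation repeated 20
  times** for random forest and multilayer perceptron classifiers
  (grid-tuned by subject-wise inner CV; stress = positive class), with
  session-level undersampling and per-group models;
* exact **TreeSHAP feature attribution** (C++; local accuracy to machine
  precision) aggregated into importance rankings across repeats;
* **ΔHRV statistics**: within-subject stress − relaxation differences,
  compared across groups by homogeneity-routed one-way ANOVA (Fisher +
  Bonferroni or Welch + Games-Howell), with η² and Cohen's d.

All randomness flows from explicit integer seeds; identical configuration
reproduces bit-identical results.

## Worked example

```r
library(hrvstress)

cfg <- cohort_config(n_per_group = c(MDD = 6, PD = 6, HC = 8), n_visits = 3,
                     visit_drift_sd = 120, retention_prob = 1, seed = 42)
cohort <- generate_cohort(cfg)
cohort
#> <hrv_cohort> 300 series, 60 sessions, 20 participants

features <- extract_cohort_features(cohort)   # 300 rows x 20 features
spec <- model_spec("random_forest", grid = 100L, seed = 42)

repeated_cv(features, spec, k = 5, repeats = 3,
            scaling_mode = "train-zscore", base_seed = 42)
#> <cv_result> random_forest, 5-fold x 3 repeats, scaling = train-zscore
#>   accuracy [HC]: 0.6667 +/- 0.0601
#>   accuracy [MDD]: 0.5444 +/- 0.0509
#>   accuracy [overall]: 0.5944 +/- 0.0210
#>   accuracy [PD]: 0.5611 +/- 0.0536

cv_scaled <- repeated_cv(features, spec, k = 5, repeats = 3,
                         scaling_mode = "longitudinal", base_seed = 42,
                         collect_shap = TRUE)
cv_scaled
#> <cv_result> random_forest, 5-fold x 3 repeats, scaling = longitudinal
#>   accuracy [HC]: 1.0000 +/- 0.0000
#>   accuracy [MDD]: 0.8444 +/- 0.0096
#>   accuracy [overall]: 0.9333 +/- 0.0000
#>   accuracy [PD]: 0.9111 +/- 0.0192
```

The day-to-day drift swamps the task effect, so conventional train-fold
z-scaling leaves the classifier near chance for the patient groups, while
per-participant longitudinal scaling removes the between-subject baseline
differences and lifts overall accuracy from 0.59 to 0.93 — with healthy
controls (whose reactivity is configured about twice the patients') most
separable in both regimes. Which features the scaled model relies on, and
how groups differ in reactivity:

```r
head(aggregate_importance(cv_scaled, regime = "scaled")[,
     c("feature", "mean_abs_shap", "rank")], 5)
#>  feature mean_abs_shap rank
#>   log_lf    0.12466377    1
#>    lf_hf    0.08256549    2
#>    lf_nu    0.07837892    3
#>    hf_nu    0.07611321    4
#>   alpha1    0.02953973    5

rs <- reactivity_summary(delta_hrv(features))
rs[rs$feature %in% c("mean_rri", "log_hf"), c("feature", "F", "p", "direction")]
#>   feature        F            p    direction
#>  mean_rri 17.18283 5.078801e-06 HC > MDD, PD
#>    log_hf 40.47568 1.148798e-11 HC > MDD, PD
```

The ΔHRV table reads: the group main effect on the stress-minus-relaxation
change is significant for both features, and controls change more (in
absolute terms) than either patient group.

A thin command-line wrapper over the same functions ships in
`inst/scripts/hrvstress-cli.R` (subcommands `simulate`, `extract`, `scale`,
`classify`, `stats`, `run`).

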