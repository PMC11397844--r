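# digibm

Digital-biomarker feature engineering and screening models for wearable
sensor assessment batteries.

Early-stage Parkinson's disease (PD) is underdiagnosed: clinical
evaluation is subjective, rater-dependent and infrequent, and access to
screening is limited. Consumer smartwatches and smartphones can record
the motor and non-motor signals that matter — tremor-band accelerometry,
gait dynamics, voice perturbation, tapping rhythm, drawing tremor,
working memory — frequently and objectively, at home. `digibm` is an R
toolkit for turning those raw sensor streams into a screening model and
for auditing that model the way a remote-monitoring study must: with
subject-wise cross-validation, clinic-vs-home generalization checks, and
feature-level reliability.

The package is aimed at digital-biomarker methodologists and
biostatisticians who need a complete, testable reference pipeline. Since
real study data of this kind are access-restricted, a synthetic-cohort
generator (with persisted ground truth) stands in for the device
streams, and the entire pipeline is exercised end to end on it.

## What it computes

**Feature catalog (3621 features per session)** across nine assessments:

| assessment | features | core routines |
|---|---|---|
| Tremor (postural, resting) | 462 | zero-cross & inter-cross stats, path lengths, convex hulls, tremor-band (4–10 Hz) energies, roll-offs, MFCC 1–16, spectral-shape stats |
| Gait & Balance | 2106 | the tremor catalog per device + FIR step detection, per-step stats, 15-pair watch–phone spectral coherence |
| Phonation / Articulation | 495 each | f0, HNR, jitter (ms, %), shimmer (dB, %), band energies, roll-offs, MFCC 1–16, 13 stats across 15 segments |
| Finger Tapping | 28 | tap timing/position distributions, isochrony, peak tap frequency |
| Fine Motor | 19 | path/rotation ratios, speed, 4–10 Hz tracing energy |
| Trails | 12 | completion time, path length, RMSE to the idealized path, 4–10 Hz energies |
| VSTM / SDMT | 2 each | accuracy, Cowan's K = set size × (hit − FA); totals |

**Analyses**: per-feature univariate selectivity (F statistic at
α = 0.05, uncorrected); Monte-Carlo subject-wise 90/10 cross-validation
of nine classifiers × four feature-processing cells (±top-100 selection,
±10-component PCA), with Wilcoxon-based model selection under a
parsimony rule; impurity-based random-forest feature importance;
record-wise vs subject-wise split inflation; a 2×2×2
clinic/home × same/independent-cohort generalization experiment with
repeated-measures ANOVA; and ICC(2,1) external and test-retest
reliability against a 0.6 threshold.

## Worked example

```r
library(digibm)

# a small synthetic study: 8 PD + 8 HC, one clinic + two home visits,
# a four-assessment battery
spec <- cohort_spec(n_pd = 8, n_hc = 8, n_clinic_visits = 1,
                    n_home_visits = 2,
                    battery = c("tremor", "finger_tapping", "vstm", "sdmt"),
                    tremor_duration = 6, effect_scale = 1, seed = 42)
cohort <- generate_cohort(spec)
features <- extract_cohort(cohort$sessions, battery = spec$battery)
dim(features)
#> [1]  48 499    # 48 sessions x (5 key columns + 494 features)

matrix <- build_matrix(features)          # one averaged row per participant
sel <- selectivity_analysis(matrix)
round(100 * attr(sel, "prop_significant"), 1)
#> [1] 29.4       # % of features separating PD from HC at p < 0.05

mc <- monte_carlo_cv(matrix, iters = 20, seed = 42,
                     models = c("LR", "RF", "GNB"))
select_model(mc)
#> # A tibble: 1 x 5
#>   model selection reduction median_accuracy n_candidates
#>   <chr> <lgl>     <lgl>               <dbl>        <int>
#> 1 LR    FALSE     FALSE               1            12
```

With 16 well-separated synthetic participants the 2-participant test
folds are classified perfectly by most cells, so the Wilcoxon screen
cannot distinguish them and the parsimony rule falls back to the least
complex model with no feature processing. At larger scale (see
`scripts/acceptance.R`) the cells separate.

Results objects follow broom/ggplot2 conventions: `tidy()` gives
per-iteration metrics, `glance()` per-cell summaries, and `autoplot()`
standard figures (accuracy by model, importance CDFs, reliability bars).

A thin CLI wraps the same functions (installed to `exec/`):

```sh
digibm simulate --seed 1 --n-pd 4 --n-hc 4 --out cohort/
digibm extract --sessions cohort/ --out features.csv
digibm compare-models --features features.csv --iters 100 --seed 1 --out results.json
```

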