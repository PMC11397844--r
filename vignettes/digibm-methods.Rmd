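---
title: "Methods: sensor feature engineering and screening models in digibm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensor feature engineering and screening models in digibm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model of the data

`digibm` implements a screening pipeline for early-stage Parkinson's
disease (PD) built on a multidomain mobile assessment battery: nine
assessments (visual short-term memory, symbol–digit matching, trail
making, fine motor drag-and-rotate, finger tapping, phonation,
articulation, tremor, and gait/balance) recorded on a consumer smartwatch
and smartphone. Each participant-visit is a *session*; a participant
contributes clinic sessions (supervised) and home sessions
(self-administered). From every session the package engineers a fixed
catalog of 3621 named features, partitioned
2/2/12/19/28/495/495/462/2106 across
VSTM/SDMT/Trails/Fine&nbsp;Motor/Finger&nbsp;Tapping/Phonation/Articulation/Tremor/Gait-Balance.
Downstream, the catalog feeds four analyses: univariate feature
selectivity, a Monte-Carlo subject-wise cross-validated comparison of
nine classifiers under parametric feature processing, a clinic-vs-home
cross-environment generalization experiment, and intraclass-correlation
(ICC) reliability.

The real study data behind this design are access-restricted, so the
package ships a synthetic-cohort generator whose outputs carry the
statistical structure those analyses assume. Everything below documents
the concrete estimators, their parameters, and the choices made where the
methodology leaves details open.

## Motion preprocessing

**Reference frame.** Accelerometer traces arrive in the device frame.
Gravity is estimated as the mean of the 0.3&nbsp;Hz zero-phase low-pass
filtered signal, and the trace is rotated by the minimal-angle (Rodrigues)
proper rotation taking that direction onto +z, so the z-axis is normal to
the surface plane. The rotation is orthonormal with det&nbsp;=&nbsp;+1 and
preserves each sample's Euclidean norm to machine precision; a test
enforces 1e-9. The estimator (low-pass mean + Rodrigues) is our choice —
the methodology fixes the goal, not the algorithm.

**Integration.** Velocity and position are first and second *cumulative
trapezoidal* integrals over the actual timestamps, with zero initial
conditions. No drift correction or detrending is applied, deliberately:
path-length features operate on the raw integrals, so position-derived
features partly reflect low-frequency drift. This mirrors the literal
processing description the pipeline reproduces; it is a known limitation.

**Synchronization.** Watch and phone traces are linearly interpolated
onto a shared uniform 100&nbsp;Hz clock over their overlapping interval.

**Step detection.** The gait pipeline is: 10&nbsp;Hz high-pass FIR per
axis → Euclidean modulus → 5&nbsp;Hz low-pass FIR → second time
derivative → candidates where the value exceeds 1.15× the mean of the
*rectified* processed signal → runs of consecutive supra-threshold
samples collapse to the run maximum → a 300&nbsp;ms refractory period →
steps arriving more than 1000&nbsp;ms after the last retained step are
excluded and counted. Open details we fixed: (1) "15% above the mean" is
interpreted against the rectified post-derivative signal (the raw second
derivative has near-zero mean, which would make the threshold
meaningless); both the factor and the reference are arguments to
`detect_steps()`. (2) The FIRs are order-100 Hamming windowed-sinc
filters applied forward–backward (zero phase). (3) The refractory period
is 300&nbsp;ms rather than a smaller value: after the zero-phase 5&nbsp;Hz
low-pass, a single strike's envelope exhibits two curvature flanks
roughly 270&nbsp;ms apart, and a shorter refractory double-counts every
strike; 300&nbsp;ms still resolves cadences beyond 2.2&nbsp;steps/s.
(4) When a long inter-step gap is excluded, the *later* step is dropped,
which guarantees every retained interval is ≤ 1000&nbsp;ms.

## The feature catalog

**Univariate time domain (20 per axis).** Zero-cross rate of the
mean-centred acceleration (exact zeros count once); eight summary
statistics (median, mean, Q1, Q3, IQR, SD, kurtosis, skewness) of
inter-cross intervals in ms; SD and IQR of raw acceleration; mean,
median, SD, Q1, Q3, IQR of velocity; total path length (sum of absolute
successive differences) of acceleration, velocity, position. Kurtosis is
*excess* kurtosis (normal → 0) and skewness the adjusted Fisher–Pearson
estimator throughout the package; the methodology is silent on the
estimator, so this is flagged here once.

**Multivariate time domain (24 per device).** Total path length (sum of
Euclidean step norms) and convex-hull area for each axis combination
(x-y, x-z, y-z, x-y-z) of acceleration, velocity and position. 2-D hulls
are polygon areas (`grDevices::chull` + shoelace); the 3-D hull's
*surface area* comes from a quickhull implementation written for this
package (no 3-D hull package is available in our dependency set), tested
against a brute-force facet-enumeration oracle.

**Univariate frequency domain (49 per axis).** The PSD is a Welch
estimate: Hann window, 5-s segments, 50% overlap, with a tail-flush final
segment so the whole record is used; a 10-s tremor record is therefore
analysed as roughly two segments. Features: energies in seven 1-Hz bands
from 3.5 to 10.5&nbsp;Hz plus the 4–10&nbsp;Hz tremor band (band energy =
PSD integral over the band, so partitions are additive to within
numerical tolerance); spectral roll-off at 1/25/50/75/99% of total power;
MFCC 1–16 over 0–49&nbsp;Hz (32 triangular mel filters, log energies,
orthonormal DCT-II, 0th coefficient excluded, hence amplitude-invariant);
and five statistics (entropy with natural log on the normalised PSD, SD,
kurtosis, skewness, flatness = geometric/arithmetic mean) of four
spectral views — full 0–49&nbsp;Hz, within 4–10&nbsp;Hz, outside
4–10&nbsp;Hz, and the in-band spectrum normalised by total out-of-band
energy. The fourth "ratio" view is our construction: the source counts
four views but only names "the ratio", which is not itself a spectrum.

**Coherence (285).** Magnitude-squared coherence from Welch
cross-spectra on the synchronized 100&nbsp;Hz clock, same segmentation.
For each of the 15 unordered pairs among the six channels (watch x/y/z,
phone x/y/z): peak-coherence frequency, total coherence (sum over bins —
"sum vs integral" was unspecified; we sum), and coherence at 1–10, 15,
20, 25, 30, 35, 40, 45&nbsp;Hz.

**Gait events (51 per axis per device).** Step count, step frequency
(count/duration), total per-axis step distance, then eight summary
statistics of six per-step-window quantities: inter-step interval, step
velocity, step distance, and path length of acceleration, velocity,
position inside each window. Step distance is per-axis displacement
(matching the per-dimension accounting of the catalog), not the 3-D norm.
Balance records run the identical catalog; with ≈0 steps the step-window
moments are undefined and emitted as missing values — the only missing
values a complete session produces.

**Voice (495 per task).** Clips are split into 15 equal segments; 38
descriptors per segment; 13 statistics (mean, median, Q1, Q3, IQR, p1,
p99, p99−p1, SD, kurtosis, skewness, flatness, RMS) across segments plus
total speech duration. The p99−p1 spread is our reading of an otherwise
undefined "IQR_99". Descriptors: f0 by FFT autocorrelation (50–500&nbsp;Hz
search, voicing threshold 0.3, parabolic peak refinement; unvoiced
segments give missing values, and summaries skip missing); HNR =
10·log10(r/(1−r)) at the f0 lag with the finite-window taper bias
n/(n−lag) removed; local jitter (ms and % of mean period) and local
shimmer (dB and %) from cycle boundaries found by upward zero crossings
of the f0-band-passed waveform with per-cycle peak amplitudes from the
raw waveform; seven band energies 50–4000&nbsp;Hz; flatness, entropy,
variance, skewness, kurtosis of the spectrum; roll-offs at 25/50/75/90%;
MFCC 1–16 (32 mel filters over 0–4000&nbsp;Hz). Speech duration uses
25-ms frames thresholded at −25&nbsp;dB below the peak frame. Kurtosis
and skewness of an exactly constant cross-segment vector are defined as
0 so a stationary fully voiced clip yields no missing summaries.
Articulation clips run the identical catalog.

**Touch and trials.** Irregular touch streams are linearly resampled to
60&nbsp;Hz and linearly detrended before any spectral estimate — the slow
traversal of the screen otherwise leaks into the 4–10&nbsp;Hz band.
Finger tapping (28): per hand, alternating/total/ratio counts, median and
IQR of tap duration, tap-to-target distance, onset asynchrony (absolute
deviation from the best-fit isochronous grid — the measure is named but
not defined in the source), inter-tap interval, IQR of sliding 10-tap
window spatial variance (vertical, horizontal), and the peak spectral
frequency of the binarized onset series. Fine motor (19): totals and
ratio, plus per hand path length, path ratio to the idealized
piecewise-linear path, speed, total rotation, rotation ratio (minimal
angular distance assumed for the idealized rotation), rotation speed, and
4–10&nbsp;Hz energies of the two position tracings. Trails (12): per
sub-task, completion time, path length, RMSE of perpendicular
point-to-segment distance to the idealized path, and 4–10&nbsp;Hz
energies of the vertical, horizontal and residual series. VSTM: accuracy
and Cowan's K = 4·(hit − false-alarm), the standard capacity estimate for
single-probe change detection at set size 4. SDMT: total completed and
accuracy.

## Synthetic cohorts

The generator is first-class, tested code: every downstream analysis is
exercised on cohorts it produces, with the injected parameters persisted
as ground truth. Signal families are the simplest generators whose
features the catalog is designed to detect:

* **Tremor**: gravity on a tilted axis + a 4–10&nbsp;Hz sinusoid on an
  orthogonal axis + white and 1/f noise. In-band power scales with
  amplitude².
* **Gait**: a shared step clock drives ~30-ms biphasic strike transients
  on both devices (phone strongest on the vertical axis); the watch adds
  an arm-swing sinusoid at half the step rate. The shared clock makes
  cross-device coherence peak on the step-frequency line and its
  harmonics.
* **Voice**: a glottal pulse train with fractional-sample pulse
  placement, per-period length and log-amplitude perturbations, a
  low-pass voiced envelope, and additive noise set by the target HNR. The
  perturbation SDs are calibrated so the injected jitter-% and
  shimmer-dB equal the *expected values of the local estimators* (for
  iid normal period noise, E|ΔT| = σ·√2·√(2/π)), which is what makes
  recovery tests meaningful.
* **Touch**: taps are a renewal process alternating between two fixed
  targets; paths follow the idealized segment chain at constant speed
  with a perpendicular 4–10&nbsp;Hz perturbation; the fine-motor drag adds
  a linear rotation ramp.
* **Cognition**: Bernoulli trial tables with given hit/false-alarm or
  accuracy rates.

Group differences enter only through shifted parameter distributions
(e.g. PD tremor amplitude log-normal with a 10× higher median at the
strong preset), never through deterministic labels, so classifiers face
realistic overlap. Each subject carries a multiplicative log-normal
random effect per parameter, shared across sessions — the ingredient that
makes record-wise cross-validation leak identity. An optional `env_shift`
perturbs motor parameters at home to emulate environment effects; it
defaults to 0.

Defaults mirror the study design: 82 PD / 50 HC participants, 6 clinic
visits (months 0/1/3/6/9/12) and 24 biweekly home visits, 100&nbsp;Hz
motion, 32&nbsp;kHz audio, 10-s tremor records, 15-s voice clips. The
source reports no effect-size magnitudes for any modality, so the strong
preset's separations (e.g. jitter 0.5→2%, arm swing 0.15→0.05&nbsp;g,
inter-tap interval 180→250&nbsp;ms) were chosen once as a plausible
early-stage contrast and are documented in `param_table()`; they are
generator settings, not claims about PD physiology.

## Modeling pipeline

Session features are averaged per participant (NA-skipping) into one row
per participant; scope can restrict to clinic or home sessions.
Selectivity is a per-feature univariate linear regression of feature on
group — computed in closed form as the squared pooled-variance t (a test
verifies the identity against `lm`) — at α = 0.05 with *no*
multiple-comparison correction, deliberately. Feature selection retains
the top 100 features by F (ties broken by F descending, then name
ascending, for determinism); reduction is PCA to 10 components on
z-scored features. Both are fitted on training rows only; a permutation
probe in the test suite verifies no test-side information reaches them.
Missing values are imputed with training-set medians. The claim that
participant averaging "normalises" features is not operationalized: no
normality transform is applied.

Nine classifiers form the grid: ridge-penalized logistic regression
(glmnet, α=0, λ=1/n — the conventional default regularization; an
unpenalized fit is undefined under perfect separation), LDA, RBF SVM,
CART decision tree, gradient-boosted trees (xgboost, 100 rounds, depth 3,
η=0.1), random forest (ranger, 100 trees, Gini impurity), a small
SGD-trained logistic regression written in-package (20 epochs, lr 0.05,
L2 1e-4; no SGD classifier exists in our dependency set), Gaussian naive
Bayes, and a small single-hidden-layer perceptron (nnet, 5 units, decay 1e-4, 100 iterations).
Scale-sensitive learners receive z-scored inputs (training statistics);
tree learners raw values. Each Monte-Carlo iteration draws one stratified
subject-wise 90/10 split — stratification is our addition; without it
some test folds contain one class and are unscorable — and all
9 × 4 cells share it. Metrics come from the 2×2 table with PD positive;
AUC is the Mann–Whitney rank statistic of the scores per iteration
(cross-checked against pROC), summarized by median and IQR.

Model selection: the top cell by median accuracy anchors a candidate set
of cells statistically indistinguishable from it (paired two-sided
Wilcoxon signed-rank on the per-iteration accuracies, α = 0.05, no
correction — accuracy only; using further metrics for the ranking was
left open and we chose not to); within candidates, fewest processing
steps wins, then the documented complexity order LR < LDA < GNB < SGD <
DT < SVM < RF < GBT < MP. Random-forest feature importance is
mean-decrease-in-impurity, normalized to sum 1, with cumulative
importance curves per assessment or per device against the chance
diagonal.

The record-wise vs subject-wise demonstration runs one identical
pipeline with session-level and participant-level splitting; with
subject random effects and zero group effect, record-wise accuracy rises
well above the chance-level subject-wise accuracy, reproducing the
methodological critique that motivates subject-wise validation.

## Cross-environment design and reliability

Participants with both clinic and home feature vectors enter a 2
(training environment) × 2 (test environment) × 2 (same vs independent
cohort) design; cohort splits are re-randomized each iteration (the
design implies but never states this; we re-randomize). "Same cohort"
means the training participants; predictions where training and test
data coincide exactly are computed but flagged (`overfit_flag`) and
quarantined from inference. A repeated-measures ANOVA
(`aov` with an `Error(iteration/...)` stratum) treats iterations as the
repeated unit, matching F(1, iters−1) degrees of freedom; with
identical accuracies in every cell the table degenerates to F=0, p=1 by
construction.

Reliability uses ICC(2,1) — two-way random effects, absolute agreement,
single measurement — computed from the two-way ANOVA mean squares. The
form is our choice (the question is absolute agreement across
environments and time); no ICC implementation exists in our dependency
set, so the formula is implemented directly and verified against the
variance-ratio σ²b/(σ²b+σ²e) in simulation (±0.05 at n = 500). External
reliability contrasts each participant's clinic mean with their home
mean; test-retest averages sessions within 30-day calendar bins and uses
bins as occasions (the source's "time bins" are undefined; monthly gives
≈12 occasions over a one-year design). Incomplete subject×occasion rows
are deleted listwise, and single-bin participants are dropped with a
count. Threshold summaries report the proportion of feature ICCs
strictly above 0.6 and a one-sided one-sample t-test of mean ICC > 0.6,
per assessment, optionally restricted to the top-importance features.

## Numerical choices and degenerate inputs

* Quantiles are R type-7 everywhere.
* Welch PSD scaled so ∫PSD df equals the signal variance; a Parseval
  test enforces 1% agreement on a single-segment estimate.
* Spectral entropy uses natural log; flatness clamps at a 1e-300 floor.
* Zero-variance features are dropped before scale-sensitive model fits;
  PCA maps zero-SD columns to SD 1.
* `icc` on a zero-between-subject-variance matrix warns and returns 0.
* A failed classifier fit yields missing scores, which propagate to
  missing metrics rather than errors.
* Hull computations tolerate degenerate (collinear/coplanar) clouds by
  returning area 0.
* All generators and analyses are pure functions of (parameters, seed);
  per-stream child seeds keep signal classes independent.

## Problem sizes used by the tests and acceptance run

The shipped tests and the acceptance script exercise the pipeline at a
reduced scale chosen by us: cohorts of 40 participants (20 PD / 20 HC)
with 1 clinic + 2 home visits on a four-assessment battery
(tremor, finger tapping, VSTM, SDMT; ≈500 features), 20 Monte-Carlo
iterations, 6-s tremor records; parameter-recovery runs use 30–50 seeds.
Catalog accounting always runs on a complete nine-assessment session at
the full study signal scales. These sizes are statistically adequate for
the properties tested (calibration of a null, direction and rough
magnitude of effects) but are not the study's 132-participant scale.

## Known limitations

* The raw-data dialects (CSV columns, YAML manifests) are a documented
  stand-in; the original acquisition platform's formats are not public.
* Position-derived features include integration drift by design.
* The voice generator has no phonetic content; articulation is an
  amplitude-modulated pulse train, so articulation features measure the
  same acoustics as phonation on modulated input.
* Synthetic cohorts cannot establish clinical validity: passing tests
  show the estimators recover what the generator injected and that the
  statistical machinery is calibrated, not that the features separate
  real PD from controls.
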