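---
title: "Dynamic plantar pressure analysis for knee OA screening: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic plantar pressure analysis for knee OA screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insolegait)
```

## The problem

Radiological knee osteoarthritis (ROA) is diagnosed from weight-bearing
radiographs (modified Kellgren–Lawrence grade ≥ 2), which capture static
joint structure only. Gait carries complementary dynamic information: knee
degeneration changes how load is applied and transferred through the foot
during walking. This package implements a complete, reproducible pipeline
that turns raw recordings from an eight-region pressure insole sampled at
20 Hz into a subject-level feature vector of 210 dynamic plantar pressure
features, screens those features statistically, and trains classifiers
that separate ROA from non-ROA walkers.

Because raw recordings from such devices are rarely shareable, the package
also contains a first-class synthetic generator that emulates the
statistical structure the analysis assumes. Every downstream stage is
developed and tested against it.

## The recording model

One subject walks several straight passes on a level walkway wearing
instrumented insoles. Each foot produces a `T × 8` matrix of regional
pressures (kPa): sensor 1 under the great toe, 2–4 under the metatarsal
heads (first; second/third; fourth/fifth), 5–6 under the medial/lateral
midfoot, 7–8 under the medial/lateral heel. Sensor coordinates live in a
foot-local frame — `y` anterior-positive, `x` lateral-positive — so
left/right centre-of-pressure statistics are directly comparable
(`sensor_layout()`).

### The synthetic stance waveform

Each clean stance cycle is a sum of raised-cosine activation bumps,
`p_r(u) = A_r · ½(1 + cos(π (u − τ_r) / w_r))` on `|u − τ_r| ≤ w_r`, with
`u` the fraction of stance. Heel sensors peak near 20 % of stance, midfoot
near 42 %, metatarsal heads near 70 %, the toe near 85 %. Peak timing is
snapped to the sample grid so each region attains its amplitude exactly at
one sample. Summing regions yields the bimodal total-force curve of normal
walking — a loading-response peak, midstance unloading, and a push-off
peak — which is exactly the shape the validity screen downstream assumes.
A configurable fraction of cycles (default 6 %) is generated *corrupted*:
all regions collapse onto a single midstance bump, so the total-force
curve is unimodal and must be rejected by preprocessing.

Default amplitudes (330/300 kPa heel, 150–200 kPa metatarsal, 220 kPa
toe, 85–90 kPa midfoot) and stance duration (0.65 ± 0.05 s, ~13 samples
at 20 Hz) are taken from the adult gait literature; the device's cohort
paper reports no regional magnitudes, so these are configurable defaults,
not fitted values. Six passes of 18 cycles per foot give each recording a
comfortable margin over the 60 valid cycles preprocessing must deliver
after trimming and corruption.

### Cycle-to-cycle variability and group effects

Variability has four seeded sources, each a fraction of the relevant mean:

* independent per-region amplitude jitter (`amp_cv`, 13 %; 18 % midfoot —
  the most variable region in insole data);
* a *shared forefoot push-off* jitter (`peak2_sd`) multiplying sensors
  1–4 together, which moves the second total-force peak;
* a *lateral-heel peak-pressure* jitter (`heel_ppp_sd`) applied as a
  zero-sum perturbation localised at the sensor-8 peak sample (shape
  `[−¼, −¼, 1, −¼, −¼]·δ` around the peak), which moves the cycle's peak
  pressure by exactly `δ` while leaving its impulse unchanged and its
  maximal gradients almost unchanged;
* an *A/P COP dispersion* jitter (`ycop_sd`): the per-sample spatial
  shares of total force are time-warped about midstance, slowing or
  speeding the heel-to-toe progression of the pressure distribution. The
  per-sample total force is preserved exactly, so peaks, valley, timing
  and every whole-foot parameter are untouched; only the within-stance
  spread of the COP trajectory changes.

In the ROA group three of these jitters are scaled by `roa_mult`:
lateral-heel peak SD on the left foot (×1.6), push-off SD (×3.0) and COP
warp SD (×2.0) on the right. This places the group signal primarily in
the SD-over-cycles of left heel peak pressure, right second peak, and
right A/P COP dispersion — the gait-stability markers the screening stage
is meant to find — alongside the demographic differences (ROA older,
higher BMI). The multipliers were chosen once, by measuring per-feature
standardised group differences on development cohorts, so that the three
targeted features carry strong effects (d ≈ 1–2.6) while their
unavoidable mechanical by-products (e.g. toe-region gradient SDs from the
COP warp, left first-peak SD from the heel jitter) stay mostly at or
below the age effect (d ≈ 0.9). Perfect isolation is impossible: second-
peak variability *is* forefoot pressure variability, and COP dispersion
cannot change without regional pressures changing; real cohort data shows
the same correlated structure.

Demographics are drawn per group (age 59.8 ± 7.9 vs 66.6 ± 7.5 years,
BMI 23.7 ± 3.1 vs 25.4 ± 3.6 kg/m²; weight derived from BMI and height so
the BMI identity holds to rounding). `null_sim_config()` zeroes all group
differences for calibration studies.

All randomness flows from one integer seed; per-subject streams are
derived by stable integer mixing of the subject index, so any subject can
be regenerated independently and cohorts are bit-reproducible.

## Preprocessing

`preprocess_recording()` chains four steps per foot:

1. **Stance detection** — maximal runs with total force above 5 % of the
   foot's maximum; duration gate 0.3–2.0 s (robust at 20 Hz, where a
   stance spans ~12–20 samples). Sample indices are 0-based, half-open.
2. **Midgait trimming** — within each walkway pass, candidates touching a
   pass boundary plus the first and last 2 candidates are discarded as
   acceleration/deceleration cycles. The trimming count is configurable;
   2 per end is our operationalisation, as the cited midgait practice
   does not fix a number.
3. **Bimodality screen** — the 3-sample moving-average of the total-force
   curve, padded with one zero per side (force is ~0 in swing, so a peak
   on the first or last stance sample is real), must show exactly two
   local maxima at ≥ 30 % of the curve maximum with the valley between
   them below 90 % of the smaller peak.
4. **Selection** — the temporally first 60 valid cycles. Fewer than 60 is
   a loud error stating per-foot counts: we neither pad nor resample,
   since silently analysing fewer cycles than the protocol requires would
   bias every SD feature. "60 cycles" is enforced *per foot*, the only
   reading consistent with independent left/right features downstream.

## The 210-feature catalogue

For each foot and each valid cycle, 45 parameters are computed:

* per region `r`: peak plantar pressure `PPP_r = max_t p_r(t)` (kPa);
  maximal/minimal pressure gradient from forward differences of the raw
  samples × sampling rate (kPa/s; smoothing is used for peak *location*
  only, never for gradients); impulse `IMP_r` as the pressure–time
  integral over stance (kPa·s), with the signal taken to rise from and
  return to zero over one sample at each boundary (so a k-sample
  rectangular pulse integrates to `k·dt·amplitude`, and regional impulses
  sum to the total-force integral to machine precision);
* whole-foot: the two bimodal peaks and intermediate valley of total
  force, their times from stance start, stance time `(L−1)/fs`, loading
  rate `peak1/t_peak1`, unloading rate `peak2/(stance_time − t_peak2)`
  (denominators floored at one sample period for boundary peaks), and the
  medial-to-lateral impulse ratio `(IMP_2+IMP_5+IMP_7)/(IMP_4+IMP_6+IMP_8)`
  — sensors 1 and 3 are treated as central and excluded;
* COP: the pressure-weighted centroid of sensor positions per sample;
  mean and SD of its two components over stance (foot-local length units;
  we do not normalise by foot length, and say so, since the hardware
  reports no foot length).

`aggregate_features()` summarises each parameter as mean and SD (n−1)
over the 60 cycles per foot (180 features, named `f_L8PPP`,
`f_RYcopstd_std`, ...), plus 30 symmetry indices on cycle-mean
parameters using the absolute Robinson form
`SI = |L−R| / (½(|L|+|R|) + ε) × 100`, ε = 1e-12 guarding the all-zero
case. The registry of 210 names is frozen and tested
(`feature_registry()`); age, gender, height, weight and BMI are appended.

## Feature selection

**Filter.** Every candidate (210 plantar + 5 physiological) is tested for
a group difference, routed by normality: Shapiro–Wilk p ≥ 0.05 in *both*
groups sends the feature to a pooled-variance two-sample t-test, anything
else to a Mann–Whitney U test with tie correction; gender uses a 2×2
chi-square (Fisher when expected counts < 5). Features are kept at raw
p < 0.05 — deliberately with **no multiple-testing correction**, matching
the screening character of the original analysis; with 215 candidates
about 11 false keeps are expected under the null, and the calibration
test verifies the routed procedure's type-I error stays within
[0.03, 0.07] across Gaussian and heavy-tailed nulls.

**Wrapper.** Kept features are ordered by ascending p-value and prefixes
of length 1..k_max (default: all kept, capped at 15) are scored by
stratified 10-fold cross-validated accuracy of the downstream classifier
(random forest by default), averaged over 3 repetitions; the chosen k
maximises mean CV accuracy with ties to the smallest k. A single 10-fold
split makes the argmax hostage to fold noise on ~69 training subjects
(one subject ≈ 1.4 % accuracy); repetition stabilises the selection while
`cv_repeats = 1` restores the plain reading. Fold assignment uses a
canonical subject ordering, so the chosen subset does not depend on the
order in which subjects appear in the table.

## Modelling and evaluation

`minimum_sample_size(k)` applies the planning rule "at least 10 training
subjects per feature under a 3:1 train:test split" —
`ceiling(10·k·4/3)`, e.g. 54 subjects for 4 features.
`stratified_split()` rounds `0.75 × class size` half-away-from-zero into
training, which reproduces the canonical 69 (37/32) / 23 (12/11)
partition of a 49/43 cohort for any seed.

Five backends are wrapped behind one interface: k-nearest neighbours
(`class`), SVM (`e1071`), random forest (`randomForest`), AdaBoost.M1
over depth-1/2 `rpart` trees (implemented in-package, as no boosting
classifier is otherwise available), and XGBoost (`xgboost`). Features are
standardised with training-set statistics for KNN and SVM only; tree
ensembles consume raw features. `train_and_tune()` runs a seeded random
search (default 50 trials) over declared per-model spaces, scored by mean
stratified 10-fold CV accuracy — accuracy, not F1, is the tuning
criterion throughout — and refits the best trial on the full training
set; budget 0 uses fixed documented defaults. Evaluation builds the test
confusion matrix with ROA positive and reports accuracy
`(TP+TN)/n` and positive-class F1 `2TP/(2TP+FP+FN)`. The positive-class
reading of F1 is the only one consistent with a published operating
point we use as a frozen test oracle: on an 11 ROA / 12 non-ROA test
set, accuracy 82.61 % together with F1 0.8000 pins down the unique
integer matrix (TP, FP, FN, TN) = (8, 1, 3, 11), which brute-force
enumeration in the test suite confirms.

`run_pipeline()` chains all stages under one config object
(unknown keys rejected; the config snapshot is embedded in the report)
and writes re-readable CSV/JSON artifacts.

## Numerical choices and degenerate inputs

* Peak detection: 3-sample moving average with shrinking edge windows;
  plateau maxima count once (first index); zero-padding admits boundary
  peaks; values are read from the raw curve within ±1 sample of the
  smoothed location.
* Ties in the wrapper's argmax go to the smallest k (`which.max`).
* Zero-total-force samples are excluded from COP statistics; a cycle with
  a single live sample reports zero COP SDs.
* Constant features are flagged degenerate and never kept; a group with
  constant values routes to Mann–Whitney (Shapiro–Wilk is undefined
  there).
* All-zero recordings detect zero stances (empty list, not an error);
  fully corrupted recordings abort at selection with per-foot counts.
* Doubles round-trip the CSV writers at 17 significant digits.

## What the tests do and do not show

The test suite (and the acceptance checks) run at these problem sizes:
single recordings of 6 × 18 cycles per foot for retention checks; 10,000
null features at n = 46 + 46 for filter calibration; 20 replicate
synthetic cohorts of 92 subjects (49/43) for end-to-end recovery; 2,000+
cycles for Monte-Carlo checks of the generator's closed-form
parameterisation. Passing them shows the pipeline is internally
consistent, calibrated under the null, and able to recover effects the
generator injects at the configured sizes. It does *not* show that the
specific features would discriminate in any real cohort: the generator's
waveforms are smooth raised cosines without the sensor drift, footwear
interaction, fatigue trends, or step-to-step correlation of real walking,
and its group effects are by construction concentrated where the analysis
looks for them.

## Known limitations

* At 20 Hz a stance holds ~13 samples; gradient features are coarse and
  timing features are quantised to 50 ms. This mirrors the hardware, but
  these features carry a large discretisation noise floor.
* The wrapper searches only prefixes of the p-value ordering, not general
  subsets; a feature ranked below an uninformative one by the filter can
  only enter together with it.
* The AdaBoost implementation is plain SAMME with resampling-free
  weighted stumps; it is adequate for tabular features of this size but
  not tuned for speed on large data.
* Left/right group effects are fixed to the sides where the original
  findings were reported; the generator does not model affected-side
  heterogeneity.
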