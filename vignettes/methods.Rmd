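---
title: "Detecting THC-induced impairment from prefrontal fNIRS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting THC-induced impairment from prefrontal fNIRS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Acute Δ9-tetrahydrocannabinol (THC) intoxication impairs cognition and
psychomotor control, but no body-fluid THC concentration tracks functional
impairment, and field sobriety tests (FSTs) developed for alcohol carry high
false-positive rates for cannabis. A promising alternative is functional
near-infrared spectroscopy (fNIRS): THC intoxication alters prefrontal
hemodynamics, and a classifier trained on short resting-state prefrontal
recordings can flag impairment objectively.

`nirsimpair` implements that analysis end to end as tested, reusable code:

1. a **synthetic crossover cohort generator** with a known latent impairment
   state, so every downstream stage is verifiable without access to trial
   data;
2. a standard **fNIRS preprocessing chain** (optical density, PCA motion
   correction, zero-phase band-pass filtering, modified Beer–Lambert
   conversion, channel quality screening);
3. **composite impairment labeling** (two clinical raters AND a
   physiology/DEQ algorithm);
4. **time-series classifiers** — a random convolutional-kernel transform
   with a ridge head and sequential feature detachment, and a 4-block
   parallel feature extractor with a cross-entropy head;
5. **participant-level nested cross-validation** with isotonic calibration,
   ensemble averaging and F1-optimal thresholding;
6. **statistical comparison**: paired stratified bootstrap against the FST
   baseline, within-participant condition contrasts, per-channel importance.

Because individual-level trial data for this design are not publicly
deposited, the package's empirical claims are about *recovery of known
synthetic truth* and *internal consistency*, not about reproducing any
particular clinical dataset.

# The synthetic cohort generator

## Design and study conditions

Each participant completes a THC and a placebo session (order randomized).
Sessions carry scans at `predose` (0 min), `postdose1` (~100 min) and
`postdose2` (~200 min); optionally `postdose3` (~230 min). At each attended
timepoint, one scan per configured paradigm (6-minute resting state and/or
block-design n-back) is simulated as a 20-channel, dual-wavelength
(760/850 nm) intensity recording at 10 Hz. Heart rate and the five 0–100
Drug Effects Questionnaire (DEQ) items are measured on a 20-minute grid over
240 minutes. Defaults were chosen once to mirror the scale and class
structure of a real crossover study of this design:

* `n_participants = 24` for desk use; at 180 participants with the default
  `scan_completion = 0.83`, the generator yields roughly 890 attended
  resting scans of which roughly 100–110 end up labeled impaired — about
  one labeled-impaired scan for every 7–8 nonimpaired scans, the imbalance
  characteristic of this design (regular cannabis users are tolerant, so
  more than half of participants never meet impairment criteria post-THC).
* `impairment_prevalence_target = 0.38` of attended post-THC scans are
  latently impaired; `p_inconsistent = 0.63` of ever-impaired participants
  are impaired at exactly one of the two postdose scans, giving the
  "inconsistently impaired" subsample used for temporal-specificity
  evaluation.
* A Beta(2, 2) tolerance latent variable attenuates each participant's
  probability of responding, preserving the target prevalence in
  expectation; dose is drawn near 35 mg (SD 12, truncated at 80 mg) and is
  metadata only — the eMethods-style dose-individualization rules are not
  modeled.
* Clinician raters flag impairment with sensitivity 0.95 / specificity
  0.98 per rater; the FST is positive with sensitivity 0.84 and
  false-positive rate 0.34 against session-level latent impairment,
  matching the operating point reported for expanded field sobriety
  testing, with an ordinal 0–4 failed-component score consistent with the
  binary call (positive ⇔ score ≥ 2) for ROC analysis.

## Hemodynamics

Per channel, oxyhemoglobin (HbO, µM) is the sum of a slow drift, sinusoidal
physiology (Mayer waves ≈0.1 Hz, respiration ≈0.25 Hz, cardiac ≈1.1 Hz,
random phases), a signal term, and white noise; HbR mirrors the signal term
at ratio −1/3 plus independent noise. The signal term is:

* **n-back**: a 12-block alternating 30-s 0-back/2-back boxcar convolved
  with a double-gamma HRF (peak 6 s, undershoot 16 s, ratio 6), amplitude
  scaled by `1 + effect_size` when impaired;
* **resting**: a band-limited (0.02–0.08 Hz) Gaussian process whose SD
  scales with `1 + effect_size` when impaired, plus a shared medial-PFC
  component whose mixing weight scales with `effect_size` (0.65 at the
  default `effect_size = 2`), elevating cross-channel correlation among
  medial channels. Both impairment signatures vanish exactly at
  `effect_size = 0`, which is the package's null condition.

The forward model maps concentrations to intensities through the modified
Beer–Lambert law (source–detector distance 30 mm, DPF 6.0 at both
wavelengths, extinction coefficients from a standard tabulation at 760 and
850 nm) and exponentiates around a positive baseline. Motion artifacts —
Laplacian-amplitude spikes shorter than 2 s and persistent step shifts,
shared across channels — are injected in optical-density space with
per-scan probability 0.25; multiplicative instrument noise is log-normal
with SD 0.005. The forward and inverse transforms share the extinction
table, and a round-trip test (artifacts and noise off) must agree to
1e−9 µM; correctness is enforced by that invariant rather than by asserting
any particular tabulated value.

The drug response in heart rate and DEQ holds a plateau (±30 min, short
Gaussian tails) around each postdose timepoint — oral dosing sustains the
effect across the ±20-minute measurement window — with mean +15 bpm and
DEQ ≈ 65 when impaired, small responses (≈+4 bpm, DEQ ≈ 18) for
non-impaired THC timepoints, and no heart-rate response under placebo. The
short tails keep predose and placebo measurements uncontaminated, which is
what makes the placebo-vs-predose contrast an honest null.

## What the generator does *not* emulate

Real optode-scalp optics, pharmacokinetic absorption curves, serial
autocorrelation in rater behavior, hair-related regional signal loss,
systemic physiology confounds (e.g. blood-pressure coupling), and
device-specific noise spectra. Passing recovery tests on this generator
demonstrates that the pipeline's machinery is correct and leakage-free, not
that the classifier would attain any particular accuracy on real
recordings.

# Preprocessing

The chain is optical density → quality screening → PCA motion correction →
band-pass filter → modified Beer–Lambert conversion. All steps are
deterministic (no RNG).

* **Optical density** uses the whole-scan temporal mean as reference by
  default (first-30-s mean and explicit references available), so OD
  columns are approximately mean-zero.
* **PCA motion correction** removes the leading principal components that
  cumulatively explain ≥ `variance_fraction` (default 0.8) of total
  variance; a fixed-component alternative is available. Because removal is
  proportional to each scan's own spectrum, residual variance remains
  proportional to total variance, which preserves the amplitude contrast
  between impaired and nonimpaired scans even though individual shared
  components (including task responses) are attenuated.
* **Band-pass** is a 3rd-order zero-phase Butterworth (applied
  forward-backward), default 0.01–0.2 Hz, which retains the resting-state
  signal band and removes cardiac pulsation. Columns are demeaned before
  filtering; DC would be rejected anyway, and demeaning avoids start-up
  transients.
* **Quality screening** is this package's own criterion (the exclusion rule
  used in practice on real data is typically device- and site-specific):
  cardiac-band (0.8–1.5 Hz) periodogram density relative to the flanking
  bands (0.5–0.8, 1.5–2.5 Hz), winsorized at 5 MADs so short spikes do not
  flood the broadband floor. Channels below prominence 2.5 or above a
  variance ceiling fail; scans with more than 4 failing channels are
  dropped. The defaults separate generator channels (prominence ≈ 4–5)
  from cardiac-free noise (≈ 1) and were calibrated only on synthetic data.
* **MBLL conversion** solves the 2×2 extinction system per channel and
  sample; it is linear in OD, and the whole chain is linear up to the
  (linear) filter, so scaling raw OD scales hemoglobin equally.

Screening runs on the raw OD of the first wavelength, *before* motion
correction and filtering, because the cardiac band it relies on is exactly
what the later stages remove.

# Impairment labeling

Ground truth at a postdose scan is the conjunction of three observable
flags: two independent clinician raters AND an algorithm combining
physiology and self-report. The algorithm is a composite-z rule,

> flag ⇔ ΔHR/σ_hr + DEQ_feel/σ_deq ≥ τ,

with ΔHR the mean heart rate within ±20 min of the scan minus the predose
mean, DEQ_feel the "feel drug" item nearest the scan, and documented
defaults σ_hr = 10 bpm, σ_deq = 30 points, τ = 2. The exact clinical
algorithm is not public; this stand-in was chosen so that study-scale
synthetic cohorts reproduce the characteristic ≈1:7 impaired:nonimpaired
class ratio, and all three constants are configurable. Realized prevalence
is monotone nonincreasing in τ (tested by sweep). The labeling module sees
only observables — never the generator's latent state.

Training classes: the impaired class is post-THC scans labeled impaired;
nonimpaired scans are of three types (postplacebo, predose, post-THC
without clear impairment), whose counts are reported. A cohort with an
empty impaired class aborts with an explicit error.

# Classifiers

Both model families expose the same interface — features in, unbounded raw
score out — so the cross-validation loop is model-agnostic.

**Random-kernel transform.** Kernels have lengths {7, 9, 11}, mean-centered
normal weights, uniform bias on (−1, 1), log-uniform dilations bounded by
the series length, optional zero padding, and a random channel subset
(log-uniform size) over the 40 concatenated HbO/HbR channels; the shared
weight vector is applied to each selected channel and summed. Two features
per kernel: PPV (fraction of convolution outputs strictly > 0 — ties count
as non-positive) and the maximum. The default bank is 2,000 kernels
(the transform family's conventional 10,000 is configurable); the
convolution core is compiled (Rcpp) and verified against a brute-force R
oracle to 1e−10.

**Ridge head.** Closed-form ridge on standardized features with
class-balanced ±(class-proportion) target encoding; the penalty is chosen
from a log-spaced grid by exact leave-one-out PRESS from a single SVD. Raw
score = linear response; the class boundary is 0.

**Sequential feature detachment.** Starting from the fitted ridge head,
each step removes the 5% (configurable) of active features with the
smallest absolute standardized weight, refits at the same penalty, and
records validation accuracy; pruning continues to a single feature, and the
returned mask maximizes `accuracy − c · fraction retained` with c = 0.1
(first maximum, i.e. the largest feature set among ties; c = 0 reduces to
the accuracy argmax). The penalty is not re-selected during pruning — at
the scale of a pruning path a per-step grid search would dominate runtime
while changing little, since the feature set shrinks gradually.

**Parallel extraction.** Four concatenated blocks per scan: (1) per-channel
moments (mean, SD, skewness, excess kurtosis) of HbO and HbR; (2)
per-channel mean periodogram density in 0.01–0.04, 0.04–0.08 and
0.08–0.15 Hz; (3) the upper triangle of the HbO cross-channel correlation
matrix, with entries involving zero-variance channels defined as 0; (4) a
64-kernel pool. The 4 submodels of the original ensemble are not publicly
specified; these blocks are this package's own definition, labeled as such.
The head is L2-penalized logistic regression fit by IRLS from zero
(deterministic), raw score = log-odds.

# Nested cross-validation and calibration

Participants — never scans — are dealt into 5 outer test folds and, within
each outer fold's training pool, 6 inner validation folds, stratified by
ever-impaired status (balanced within ±1 per class per fold; the
stratification variable is this package's choice). For each inner fold, a
submodel is trained on the other five, isotonically calibrated on the
held-out fold, and its calibrated validation scores pooled; the F1-optimal
threshold (candidates: midpoints between distinct sorted probabilities plus
{0, 1}; ties to the smallest threshold) is selected on the pooled validation
scores (a per-fold median alternative is available behind a flag). Outer
test scans are scored by the arithmetic mean of the six calibrated
probabilities and thresholded. Pooled metrics over concatenated out-of-fold
predictions and fold-averaged metrics are both reported, since either
pooling convention is defensible.

Isotonic calibration is a hand-written weighted pool-adjacent-violators fit
(ties pooled by weighted mean first), returning a nondecreasing step
function that clamps outside the fitted range; it is verified against an
exhaustive search over all monotone step functions on up-to-12-point
instances. `stats::isoreg` was not used because it has no weights and does
not average tied abscissae.

Every run audits leakage — a hard error if any test scan's participant
appears in a model that scored it — and `robustness` mode removes
participants never labeled impaired from all training/validation pools,
scoring them exclusively as test cases.

When the detached-kernel model runs inside the loop, the inner validation
fold doubles as the detachment's step-selection set and the calibration
set; this reuses the fold twice and is mildly optimistic for the
calibration map, but keeps the participant partition intact (test folds are
never touched).

# Inference

**Paired stratified bootstrap.** Two classifiers are compared on the shared
test scans: each of 1,000 resamples draws exactly the original number of
positives from the positives and negatives from the negatives (so every
resample preserves the class proportion exactly), computes all six metrics
for both, and collects paired differences. Reported per metric: observed
difference, percentile 95% CI (2.5/97.5), bootstrap SE, and the one-sided p
value "proportion of differences ≤ 0", kept verbatim from the field's
convention. For metrics where smaller is better (false-positive rate) the
mirrored proportion ≥ 0 is also reported, clearly labeled, since direction
handling is otherwise ambiguous. Resamples where a metric is undefined are
excluded for that metric and counted. Percentile (not BCa) intervals are
used deliberately, matching the procedure being emulated.

**Condition contrasts.** Outcomes (impairment probability, heart-rate
change, DEQ) are compared across predose / placebo / THC-impaired /
THC-not-impaired with a random-intercept-style estimator implemented
in-house: participant means are subtracted, centered condition means are
averaged across participants, and CIs come from a 2,000-resample cluster
bootstrap over participants. Full REML mixed-model machinery is
deliberately avoided — the estimator is transparent, dependency-free and
adequate for contrasts. Known limitation: with unbalanced condition
compositions (participants differ in which conditions they contribute),
within-participant centering attenuates contrasts slightly (≈10% at
default settings); the cluster-bootstrap CIs cover the injected effects in
the recovery tests, and the placebo-vs-predose null attains ≈95% coverage.

**Channel importance.** Each of the 20 channels is assessed independently:
a small kernel bank on that channel's HbO series alone, ridge head, mean
validation AUC across all inner folds of the plan. Channels carrying the
synthetic effect separate from uninformative channels by ≥0.1 AUC in the
recovery test; at `effect_size = 0` all channels hover near 0.5.

# Numerical choices and degenerate inputs

* Metrics with undefined denominators (no predicted positives, one-class
  labels) are `NA` with an attached reason, never silently 0.
* ROC-AUC is trapezoidal integration over the threshold-swept ROC curve and
  equals the tie-corrected rank statistic to 1e−12 (tested).
* PPV uses strict `>`; all-zero convolutions give PPV 0.
* Zero-variance feature columns are left unstandardized (scale 1) and
  receive zero weight via centering; zero-variance channels yield
  correlation 0 by convention.
* Threshold and detachment ties resolve to the first (smallest-threshold /
  largest-feature-set) candidate, documented in the respective functions.
* All randomness is owned: the generator, fold planner, kernel sampler and
  bootstrap take explicit seeds, save and restore the global RNG state, and
  identical configurations reproduce byte-identical outputs. Each scan
  records a derived seed so raw data can be regenerated lazily
  (`materialize = FALSE`) with identical bytes — the package streams scans
  through preprocessing and feature extraction without holding a full
  cohort's raw intensities in memory.

# Problem sizes used in the shipped evaluations

The package's own evaluation scripts and tests run, as their standard
conditions: a 180-participant resting-state cohort (≈890 scans, 6-minute
scans at 10 Hz) with a 1,000-kernel bank for the full-scale recovery
experiment; 30-participant, 2-minute-scan null cohorts with 200-kernel
banks (10 seeds); 200 simulated datasets of 200 scans each (1,000
bootstrap resamples) for type-I calibration of the paired bootstrap; and
40/20-participant physiology-only cohorts for contrast recovery and
null-coverage checks. These sizes were chosen to make the full evaluation
runnable on a single desktop core in minutes while leaving every
statistical check well-powered; all are configurable upward.

# Known limitations

* The clinical labeling algorithm, preprocessing parameters and the 4
  parallel submodels of the emulated analysis are not public; the package's
  versions are clearly documented stand-ins, and conclusions about them are
  internal-consistency claims.
* Pretrained time-series foundation models are out of scope: trained
  weights are not reproducible content.
* The SNIRF (HDF5) device format is not read; the package's native format
  is plain TSV plus a JSON manifest.
* The generator's impairment signature is a variance/correlation change in
  a fixed band; classifiers that exploit it are not guaranteed to transfer
  to the real neural signature of intoxication.
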