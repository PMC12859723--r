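# nirsimpair

Detecting acute THC-induced impairment from prefrontal fNIRS time series.

## The problem

No blood, saliva or urine THC concentration tracks *functional* impairment,
and field sobriety tests (FSTs) developed for alcohol have high
false-positive rates for cannabis. Acute THC intoxication alters prefrontal
hemodynamics, which functional near-infrared spectroscopy (fNIRS) measures
portably: a classifier trained on a 6-minute resting-state prefrontal
recording can flag impairment objectively, in principle more accurately than
a 45-minute behavioral exam.

`nirsimpair` is a complete, tested implementation of that analysis for
biostatisticians and neuroimaging methodologists:

* **Synthetic crossover cohort generator** — a double-blind THC/placebo
  crossover with predose and two postdose scans per session, 20-channel
  dual-wavelength (760/850 nm) raw intensities produced through a forward
  modified Beer–Lambert model, serial heart rate and Drug Effects
  Questionnaire (DEQ) ratings, clinician rater flags, and FST outcomes —
  all driven by a known latent impairment state, so every downstream stage
  is testable without any data download.
* **fNIRS preprocessing** — optical density, PCA-based motion correction,
  zero-phase band-pass filtering, modified Beer–Lambert conversion
  (ΔOD<sub>λ</sub> = (ε<sub>λ,HbO</sub>·ΔHbO + ε<sub>λ,HbR</sub>·ΔHbR)·d·DPF<sub>λ</sub>),
  and cardiac-prominence channel screening.
* **Impairment labeling** — ground truth is the conjunction: both clinical
  raters impaired AND a composite physiology/DEQ rule
  (ΔHR/σ<sub>hr</sub> + DEQ<sub>feel</sub>/σ<sub>deq</sub> ≥ τ).
* **Classifiers** — a random convolutional-kernel transform (PPV + max
  features, compiled core) with a ridge head and sequential feature
  detachment, and a 4-block parallel feature extractor (moments, band
  powers, channel correlations, kernel pool) with a cross-entropy head.
* **Evaluation** — participant-level 5-outer × 6-inner nested
  cross-validation; each inner submodel isotonically calibrated
  (pool-adjacent-violators) on its validation fold; test scans classified
  by the mean of the k calibrated probabilities at the F1-optimal
  threshold; precision, recall, F1, accuracy, false-positive rate and
  trapezoidal ROC-AUC.
* **Inference** — paired stratified bootstrap comparison against the FST
  baseline (percentile 95% CIs, SEs, and the one-sided p value "proportion
  of bootstrap differences ≤ 0"), within-participant condition contrasts
  with cluster-bootstrap CIs, and per-channel importance.

See `vignettes/methods.Rmd` for the models, assumptions, parameter
defaults and design decisions.

## Worked example

Simulate a 30-participant resting-state cohort with a strong impairment
signature, label it from observables only, run the nested-CV kernel
classifier, and compare it against the simulated field sobriety test on the
shared post-THC scans:

```r
library(nirsimpair)

cfg <- cohort_config(n_participants = 30, scan_minutes = 2,
                     scan_types = "resting", effect_size = 2, seed = 11)
coh  <- generate_cohort(cfg, materialize = FALSE)   # scans stream on demand
labs <- label_cohort(coh)                           # raters AND algorithm
cls  <- training_class_assignment(labs, coh$scan_table)

fx <- cohort_features(coh, n_kernels = 300, seed = 5)  # preprocess + transform
y  <- cls$class_impaired[match(fx$meta$scan_id, cls$scan_id)]

ever <- tapply(y, fx$meta$participant, any)
plan <- make_fold_plan(names(ever), as.logical(ever), seed = 2)
res  <- run_nested_cv(fx$x, y, fx$meta$participant, plan, model = "ridge")
res
#> Nested CV (ridge model, standard mode): 153 scans, 5 outer folds
#> Pooled out-of-fold metrics:
#> Classification metrics (n = 153)
#>           precision              recall                  f1            accuracy
#>               0.733               0.917               0.815               0.935
#> false_positive_rate             roc_auc
#>               0.062               0.938
```

Every probability in `res$scans$prob` is out-of-fold: the six submodels
that scored a scan never saw any scan from that participant (audited — a
violation is a hard error). The pooled ROC-AUC of 0.94 reflects the strong
synthetic effect; at `effect_size = 0` the same pipeline returns chance
(≈0.5).

Comparing with the FST on the shared post-THC scans:

```r
shared <- fx$meta$session == "THC" & fx$meta$timepoint != "predose"
fst    <- coh$fst[match(fx$meta$participant[shared], coh$fst$participant), ]
cmp <- paired_bootstrap(y[shared],
                        res$scans$flag[shared], res$scans$prob[shared],
                        fst$fst_positive, fst$fst_score,
                        n_boot = 1000, seed = 3)
cmp
#> Paired stratified bootstrap (1000 resamples, 53 shared scans, seed 3)
#>               metric observed_a observed_b difference ci_low ci_high    se
#>            precision      0.957      0.579      0.378  0.275   0.476 0.054
#>               recall      0.917      0.917      0.000 -0.167   0.167 0.081
#>                   f1      0.936      0.710      0.226  0.116   0.342 0.055
#>             accuracy      0.943      0.660      0.283  0.170   0.415 0.063
#>  false_positive_rate      0.034      0.552     -0.517 -0.690  -0.345 0.092
#>              roc_auc      0.945      0.684      0.261  0.109   0.435 0.082
#>  p_value p_value_mirrored n_resamples_used
#>    0.000            1.000             1000
#>    0.582            0.611             1000
#>    0.000            1.000             1000
#>    0.000            1.000             1000
#>    1.000            0.000             1000
#>    0.000            1.000             1000
```

Each row is one metric: the observed values for the fNIRS classifier (A)
and the FST (B), their paired difference with percentile 95% CI and
bootstrap SE over 1,000 stratified resamples, and the one-sided bootstrap
p value (for the false-positive rate, where smaller is better, read the
mirrored column). Here the fNIRS classifier beats the simulated FST on
precision, F1, accuracy, false-positive rate and ROC-AUC, while recall is
tied — the FST is sensitive but unspecific, exactly the behavior its
0.84/0.34 operating point encodes.

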