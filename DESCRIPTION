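Package: nirsimpair
Title: Detecting Drug-Induced Impairment from Prefrontal fNIRS Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis pipeline for classifying acute
    THC-induced impairment from prefrontal functional near-infrared
    spectroscopy (fNIRS) recordings. Provides a synthetic double-blind
    crossover cohort generator with a known latent impairment state
    (dual-wavelength optical intensities, heart rate, subjective drug-effect
    ratings, clinician ratings and field-sobriety outcomes), a standard
    fNIRS preprocessing chain (optical density, PCA motion correction,
    zero-phase band-pass filtering, modified Beer-Lambert conversion,
    channel quality screening), composite impairment labeling, random
    convolutional-kernel and parallel feature-extraction classifiers with
    sequential feature detachment, participant-level nested cross-validation
    with isotonic calibration and F1-optimal thresholding, and paired
    stratified bootstrap comparison against a field-sobriety-test baseline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
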