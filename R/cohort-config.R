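#' Configuration for a synthetic crossover cohort
#'
#' Builds and validates the configuration object consumed by
#' [generate_cohort()]. Defaults mirror a double-blind THC/placebo crossover
#' drug-challenge study: two sessions per participant at least a week apart,
#' 6-minute 20-channel dual-wavelength (760/850 nm) prefrontal fNIRS scans at
#' a predose and two postdose timepoints, serial heart-rate and 5-item 0-100
#' Drug Effects Questionnaire (DEQ) measurements on a 20-minute grid, two
#' independent clinician impairment raters, and an expanded field sobriety
#' test (FST) during each THC session.
#'
#' @param n_participants Number of participants (>= 2).
#' @param scan_timepoints Ordered scan timepoints per session. Must start with
#'   `"predose"`; supported postdose timepoints are `"postdose1"` (~100 min),
#'   `"postdose2"` (~200 min) and optionally `"postdose3"` (~230 min).
#' @param scan_types Scan paradigms to simulate: any of `"resting"`,
#'   `"nback"`. May be `character(0)` to simulate only physiology/ratings.
#' @param scan_minutes Scan duration in minutes.
#' @param sample_rate fNIRS sampling rate in Hz. `sample_rate * scan_minutes
#'   * 60` must be a whole number of samples.
#' @param n_channels Number of fNIRS channels (montage splits them evenly
#'   over five prefrontal regions, so a multiple of 5 is recommended).
#' @param wavelengths Length-2 numeric, nm (default 760, 850).
#' @param impairment_prevalence_target Target fraction of attended post-THC
#'   scans that are latently impaired, in (0, 1).
#' @param p_inconsistent Among ever-impaired participants, probability of
#'   being impaired at exactly one of the two postdose scans.
#' @param scan_completion Per-(session, timepoint) attendance probability;
#'   missed visits drop all scans at that timepoint.
#' @param effect_size Dimensionless amplitude multiplier for the impairment
#'   hemodynamic signature; impaired scans scale the signal term by
#'   `1 + effect_size`.
#' @param effect_regions Montage region labels carrying the impairment
#'   effect, or `NULL` (default) for all regions. See [build_montage()].
#' @param hr_effect_bpm Mean heart-rate elevation (bpm) over predose baseline
#'   at impaired timepoints.
#' @param deq_effect Mean "feel drug" DEQ rating (0-100 scale) at impaired
#'   timepoints.
#' @param rater_sensitivity,rater_specificity Per-rater flag probabilities
#'   given latent impairment / its absence.
#' @param fst_sensitivity,fst_false_positive_rate FST outcome probabilities
#'   given session-level latent impairment / its absence. Defaults 0.84 and
#'   0.34 reproduce the recall and false-positive rate typical of expanded
#'   field sobriety testing for cannabis impairment.
#' @param artifact_prob Per-scan probability of injected motion artifacts
#'   (spikes and step shifts in optical-density space).
#' @param instrument_noise_sd SD of multiplicative (log-scale) instrument
#'   noise on raw intensities; 0 disables.
#' @param sd_distance_mm Source-detector separation in mm.
#' @param dpf Differential pathlength factors, one per wavelength.
#' @param seed Integer RNG seed; the whole cohort is a deterministic function
#'   of the configuration.
#'
#' @return An object of class `cohort_config` (a validated named list).
#' @examples
#' cfg <- cohort_config(n_participants = 10, seed = 1)
#' cfg$n_channels
#' @export
cohort_config <- function(n_participants = 24,
                          scan_timepoints = c("predose", "postdose1", "postdose2"),
                          scan_types = c("resting", "nback"),
                          scan_minutes = 6,
                          sample_rate = 10,
                          n_channels = 20,
                          wavelengths = c(760, 850),
                          impairment_prevalence_target = 0.38,
                          p_inconsistent = 0.63,
                          scan_completion = 0.83,
                          effect_size = 2,
                          effect_regions = NULL,
                          hr_effect_bpm = 15,
                          deq_effect = 65,
                          rater_sensitivity = 0.95,
                          rater_specificity = 0.98,
                          fst_sensitivity = 0.84,
                          fst_false_positive_rate = 0.34,
                          artifact_prob = 0.25,
                          instrument_noise_sd = 0.005,
                          sd_distance_mm = 30,
                          dpf = c(6, 6),
                          seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    scan_timepoints = as.character(scan_timepoints),
    scan_types = as.character(scan_types),
    scan_minutes = scan_minutes,
    sample_rate = sample_rate,
    n_channels = as.integer(n_channels),
    wavelengths = as.numeric(wavelengths),
    impairment_prevalence_target = impairment_prevalence_target,
    p_inconsistent = p_inconsistent,
    scan_completion = scan_completion,
    effect_size = effect_size,
    effect_regions = effect_regions,
    hr_effect_bpm = hr_effect_bpm,
    deq_effect = deq_effect,
    rater_sensitivity = rater_sensitivity,
    rater_specificity = rater_specificity,
    fst_sensitivity = fst_sensitivity,
    fst_false_positive_rate = fst_false_positive_rate,
    artifact_prob = artifact_prob,
    instrument_noise_sd = instrument_noise_sd,
    sd_distance_mm = sd_distance_mm,
    dpf = as.numeric(dpf),
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  bad <- function(field, why) {
    stop(sprintf("invalid cohort_config field '%s': %s", field, why),
         call. = FALSE)
  }
  if (is.na(cfg$n_participants) || cfg$n_participants < 2L)
    bad("n_participants", "must be an integer >= 2")
  if (length(cfg$scan_timepoints) < 3L ||
      cfg$scan_timepoints[1L] != "predose" ||
      !all(cfg$scan_timepoints %in% names(timepoint_minutes())))
    bad("scan_timepoints",
        "must start with 'predose' followed by >= 2 of postdose1/postdose2/postdose3")
  if (anyDuplicated(cfg$scan_timepoints))
    bad("scan_timepoints", "must not repeat")
  if (!all(cfg$scan_types %in% c("resting", "nback")))
    bad("scan_types", "must be a subset of c('resting', 'nback')")
  if (!is.numeric(cfg$scan_minutes) || cfg$scan_minutes <= 0)
    bad("scan_minutes", "must be a positive duration")
  if (!is.numeric(cfg$sample_rate) || cfg$sample_rate <= 0)
    bad("sample_rate", "must be positive (Hz)")
  n_samp <- cfg$sample_rate * cfg$scan_minutes * 60
  if (abs(n_samp - round(n_samp)) > 1e-8)
    bad("sample_rate", "sample_rate * scan_minutes * 60 must be an integer sample count")
  if (cfg$n_channels < 1L) bad("n_channels", "must be >= 1")
  if (length(cfg$wavelengths) != 2L || any(cfg$wavelengths <= 0))
    bad("wavelengths", "must be two positive wavelengths (nm)")
  probs <- c("impairment_prevalence_target", "p_inconsistent", "scan_completion",
             "rater_sensitivity", "rater_specificity", "fst_sensitivity",
             "fst_false_positive_rate", "artifact_prob")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      bad(p, "must be a probability in [0, 1]")
  }
  if (!is.null(cfg$effect_regions) &&
      !all(cfg$effect_regions %in% pfc_regions()))
    bad("effect_regions",
        paste("must be NULL or a subset of", paste(pfc_regions(), collapse = ", ")))
  if (cfg$effect_size < 0) bad("effect_size", "must be >= 0")
  if (cfg$instrument_noise_sd < 0) bad("instrument_noise_sd", "must be >= 0")
  if (cfg$sd_distance_mm <= 0) bad("sd_distance_mm", "must be positive (mm)")
  if (length(cfg$dpf) != 2L || any(cfg$dpf <= 0))
    bad("dpf", "must be two positive differential pathlength factors")
  if (is.na(cfg$seed)) bad("seed", "must be an integer")
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic crossover cohort configuration\n")
  cat(sprintf("  participants: %d, sessions: THC + placebo\n", x$n_participants))
  cat(sprintf("  timepoints: %s\n", paste(x$scan_timepoints, collapse = ", ")))
  cat(sprintf("  scans: %s, %g min @ %g Hz, %d channels @ %g/%g nm\n",
              if (length(x$scan_types)) paste(x$scan_types, collapse = "+") else "(none)",
              x$scan_minutes, x$sample_rate, x$n_channels,
              x$wavelengths[1], x$wavelengths[2]))
  cat(sprintf("  post-THC impairment prevalence target: %.2f, effect size: %g\n",
              x$impairment_prevalence_target, x$effect_size))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Nominal minutes after dosing for each scan timepoint; predose scans
# precede dosing and anchor the physiological baseline at t = 0.
timepoint_minutes <- function() {
  c(predose = 0, postdose1 = 100, postdose2 = 200, postdose3 = 230)
}

pfc_regions <- function() {
  c("dmPFC_L", "dmPFC_R", "vPFC_L", "vPFC_R", "mPFC")
}

#' Prefrontal channel montage
#'
#' Lays out `n_channels` source-detector channels over five prefrontal
#' regions (left/right dorsomedial PFC, left/right ventral PFC, medial PFC),
#' assigning channels to regions as evenly as possible in montage order.
#'
#' @param n_channels Number of channels.
#' @param sd_distance_mm Source-detector separation (mm) recorded per channel.
#' @return A data.frame with columns `channel`, `source`, `detector`,
#'   `region`, `distance_mm`.
#' @examples
#' table(build_montage(20)$region)
#' @export
build_montage <- function(n_channels = 20, sd_distance_mm = 30) {
  regions <- pfc_regions()
  # contiguous blocks per region, remainder spread over the first regions
  region <- rep(regions, times = tabulate(
    rep(seq_along(regions), length.out = n_channels), nbins = length(regions)))
  data.frame(
    channel = seq_len(n_channels),
    source = ((seq_len(n_channels) - 1L) %/% 2L) + 1L,
    detector = ((seq_len(n_channels) - 1L) %/% 2L) + 1L + (seq_len(n_channels) %% 2L),
    region = region,
    distance_mm = sd_distance_mm,
    stringsAsFactors = FALSE
  )
}

#' Hemoglobin extinction coefficients
#'
#' Molar extinction coefficients for oxy- and deoxyhemoglobin at the two
#' operating wavelengths, expressed per micromolar per cm. Values follow a
#' standard published compilation for whole hemoglobin; their absolute
#' accuracy is immaterial to the pipeline because the forward simulator and
#' the inverse modified Beer-Lambert solver share the same table (enforced by
#' round-trip tests).
#'
#' @param wavelengths Length-2 numeric (nm); 760/850 nm are tabulated.
#' @return A 2x2 matrix, rows = wavelengths, columns = `c("HbO", "HbR")`,
#'   units 1 / (uM * cm).
#' @examples
#' default_extinction()
#' @export
default_extinction <- function(wavelengths = c(760, 850)) {
  tab <- rbind(
    "760" = c(HbO = 586.0,  HbR = 1548.52),
    "850" = c(HbO = 1058.0, HbR = 691.32)
  )
  key <- as.character(round(wavelengths))
  if (!all(key %in% rownames(tab)))
    stop("extinction coefficients tabulated only for 760 and 850 nm; ",
         "supply a custom table for other wavelengths", call. = FALSE)
  out <- tab[key, , drop = FALSE] * 1e-6  # cm^-1 M^-1 -> cm^-1 uM^-1
  rownames(out) <- key
  out
}
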