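#' Generate a synthetic crossover cohort
#'
#' Simulates a double-blind THC/placebo crossover study with a known latent
#' impairment state. Each participant contributes two sessions (THC and
#' placebo, order randomized); each attended session timepoint yields one
#' scan per configured scan type, raw dual-wavelength fNIRS intensities
#' produced through the hemodynamic forward model, serial heart-rate and DEQ
#' measurements, two independent clinician rater flags per postdose scan,
#' and an expanded field-sobriety-test outcome per THC session.
#'
#' Latent impairment is participant-driven: a Beta-distributed tolerance
#' attenuates each participant's probability of ever responding to THC, and
#' ever-impaired participants are impaired at both postdose scans or at
#' exactly one (the "inconsistently impaired"), with probability
#' `p_inconsistent`. Placebo sessions are never latently impaired. The
#' realized latent prevalence among attended post-THC scans targets
#' `impairment_prevalence_target`.
#'
#' The whole cohort is a deterministic function of `config` (including
#' `config$seed`); each scan additionally records its own derived seed so
#' raw intensities can be regenerated lazily via [scan_intensity()].
#'
#' @param config A [cohort_config()].
#' @param materialize If `TRUE` (default) raw intensity matrices are stored
#'   in the returned object (`$scans`); if `FALSE` only metadata are stored
#'   and [scan_intensity()] regenerates any scan on demand (identical bytes).
#' @return An object of class `fnirs_cohort`: a list with elements
#'   `participants` (id, tolerance, dose_mg, ever_impaired, session order),
#'   `latent` (participant, session, timepoint, impaired), `scan_table`
#'   (one row per attended scan incl. `scan_id` and `scan_seed`),
#'   `physiology` (per session: time_min, hr_bpm, deq1..deq5), `raters`
#'   (per postdose scan timepoint: rater_a, rater_b), `fst` (per THC
#'   session: fst_positive, fst_score), `montage`, `config`, and (if
#'   materialized) `scans`, a list of intensity matrices named by `scan_id`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_participants = 4, scan_minutes = 1,
#'                                      scan_types = "resting", seed = 2))
#' nrow(coh$scan_table)
#' @export
generate_cohort <- function(config, materialize = TRUE) {
  config <- validate_cohort_config(config)
  montage <- build_montage(config$n_channels, config$sd_distance_mm)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  np <- config$n_participants
  tps <- config$scan_timepoints
  post_tps <- setdiff(tps, "predose")

  # --- participants and latent impairment ---------------------------------
  tolerance <- stats::rbeta(np, 2, 2)
  dose <- pmin(80, pmax(2.5, stats::rnorm(np, 35, 12)))
  # ever-impaired probability chosen so that the expected latent impaired
  # fraction of post-THC scans matches the prevalence target: an
  # ever-impaired participant contributes 1 impaired scan if inconsistent,
  # else one per postdose timepoint.
  n_post <- length(post_tps)
  mean_flags <- config$p_inconsistent * 1 +
    (1 - config$p_inconsistent) * n_post
  p_ever <- min(1, config$impairment_prevalence_target * n_post / mean_flags)
  # tolerance attenuates the drug response while preserving the mean
  p_i <- pmin(1, 2 * (1 - tolerance) * p_ever)
  ever_impaired <- stats::runif(np) < p_i
  inconsistent <- ever_impaired & (stats::runif(np) < config$p_inconsistent)

  session_order <- ifelse(stats::runif(np) < 0.5, "THC-first", "placebo-first")
  participants <- data.frame(
    participant = sprintf("P%03d", seq_len(np)),
    tolerance = tolerance, dose_mg = dose,
    ever_impaired = ever_impaired, inconsistent = inconsistent,
    session_order = session_order, stringsAsFactors = FALSE
  )

  latent <- expand.grid(participant = participants$participant,
                        session = c("THC", "placebo"),
                        timepoint = tps,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  latent <- latent[order(latent$participant, latent$session,
                         match(latent$timepoint, tps)), ]
  rownames(latent) <- NULL
  latent$impaired <- FALSE
  for (i in seq_len(np)) {
    if (!ever_impaired[i]) next
    sel <- latent$participant == participants$participant[i] &
      latent$session == "THC" & latent$timepoint %in% post_tps
    if (inconsistent[i]) {
      which_tp <- sample(post_tps, 1)
      latent$impaired[sel & latent$timepoint == which_tp] <- TRUE
    } else {
      latent$impaired[sel] <- TRUE
    }
  }

  # --- attendance ---------------------------------------------------------
  visit <- unique(latent[, c("participant", "session", "timepoint")])
  visit$attended <- stats::runif(nrow(visit)) < config$scan_completion

  # --- physiology (heart rate + DEQ on a 20-minute grid) ------------------
  physiology <- list()
  for (i in seq_len(np)) {
    for (arm in c("THC", "placebo")) {
      key <- paste(participants$participant[i], arm, sep = ".")
      physiology[[key]] <- simulate_session_physiology(
        participants$participant[i], arm,
        latent[latent$participant == participants$participant[i] &
                 latent$session == arm, ],
        config)
    }
  }
  physiology <- do.call(rbind, physiology)
  rownames(physiology) <- NULL

  # --- clinician raters (postdose scans only) -----------------------------
  raters <- latent[latent$timepoint %in% post_tps, ]
  p_flag <- ifelse(raters$impaired, config$rater_sensitivity,
                   1 - config$rater_specificity)
  raters$rater_a <- stats::runif(nrow(raters)) < p_flag
  raters$rater_b <- stats::runif(nrow(raters)) < p_flag
  raters$impaired <- NULL
  rownames(raters) <- NULL

  # --- field sobriety test (per THC session, ~120 min post dose) ----------
  sess_imp <- tapply(latent$impaired[latent$session == "THC"],
                     latent$participant[latent$session == "THC"], any)
  sess_imp <- sess_imp[participants$participant]
  fst <- simulate_fst(participants$participant, as.logical(sess_imp), config)

  # --- scan table ---------------------------------------------------------
  scan_table <- NULL
  if (length(config$scan_types)) {
    scan_table <- merge(visit[visit$attended, c("participant", "session", "timepoint")],
                        data.frame(scan_type = config$scan_types,
                                   stringsAsFactors = FALSE))
    scan_table <- scan_table[order(scan_table$participant, scan_table$session,
                                   match(scan_table$timepoint, tps),
                                   scan_table$scan_type), ]
    rownames(scan_table) <- NULL
    scan_table$scan_id <- sprintf("%s_%s_%s_%s", scan_table$participant,
                                  scan_table$session, scan_table$timepoint,
                                  scan_table$scan_type)
    key <- paste(scan_table$participant, scan_table$session, scan_table$timepoint)
    lkey <- paste(latent$participant, latent$session, latent$timepoint)
    scan_table$impaired <- latent$impaired[match(key, lkey)]
    scan_table$scan_seed <- (config$seed %% 65011) * 32749 +
      seq_len(nrow(scan_table))
  } else {
    scan_table <- data.frame(participant = character(0), session = character(0),
                             timepoint = character(0), scan_type = character(0),
                             scan_id = character(0), impaired = logical(0),
                             scan_seed = integer(0), stringsAsFactors = FALSE)
  }

  cohort <- structure(list(
    participants = participants, latent = latent, scan_table = scan_table,
    physiology = physiology, raters = raters, fst = fst,
    montage = montage, config = config, scans = NULL
  ), class = "fnirs_cohort")

  if (materialize && nrow(scan_table)) {
    cohort$scans <- lapply(seq_len(nrow(scan_table)), function(k)
      .generate_scan_intensity(cohort, k))
    names(cohort$scans) <- scan_table$scan_id
  }
  cohort
}

# Regenerate the raw intensity matrix for scan_table row k from its seed.
.generate_scan_intensity <- function(cohort, k) {
  row <- cohort$scan_table[k, ]
  cfg <- cohort$config
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(row$scan_seed %% .Machine$integer.max)
  hb <- simulate_hemodynamics(row$impaired, row$scan_type, cfg, cohort$montage)
  hb_to_intensity(hb$hbo, hb$hbr, cohort$montage,
                  extinction = default_extinction(cfg$wavelengths),
                  dpf = cfg$dpf, sample_rate = cfg$sample_rate,
                  artifact_prob = cfg$artifact_prob,
                  instrument_noise_sd = cfg$instrument_noise_sd)
}

#' Raw intensities for one scan
#'
#' Returns the stored intensity matrix if the cohort was materialized,
#' otherwise regenerates it deterministically from the scan's recorded seed.
#'
#' @param cohort An `fnirs_cohort`.
#' @param scan_id A `scan_id` from `cohort$scan_table`.
#' @return Samples x (2 * channels) intensity matrix.
#' @export
scan_intensity <- function(cohort, scan_id) {
  k <- match(scan_id, cohort$scan_table$scan_id)
  if (is.na(k)) stop("unknown scan_id: ", scan_id, call. = FALSE)
  if (!is.null(cohort$scans)) return(cohort$scans[[scan_id]])
  .generate_scan_intensity(cohort, k)
}

#' @export
print.fnirs_cohort <- function(x, ...) {
  cat("Synthetic fNIRS crossover cohort\n")
  cat(sprintf("  %d participants, %d attended scans (%s)\n",
              nrow(x$participants), nrow(x$scan_table),
              if (length(x$config$scan_types))
                paste(x$config$scan_types, collapse = "+") else "no fNIRS"))
  post <- x$latent$timepoint != "predose" & x$latent$session == "THC"
  cat(sprintf("  latently impaired post-THC states: %d / %d\n",
              sum(x$latent$impaired[post]), sum(post)))
  cat(sprintf("  materialized: %s\n", !is.null(x$scans)))
  invisible(x)
}

# Heart rate and DEQ over 0..240 min (20-min grid). The drug response holds
# a plateau around each postdose scan time (oral dosing sustains the effect
# across the +/- 20-minute measurement window) with short smooth tails, so
# predose measurements stay uncontaminated; plateau height depends on the
# latent impairment state at that timepoint.
simulate_session_physiology <- function(participant, arm, latent_sess, config) {
  grid <- seq(0, 240, by = 20)
  hr_base <- stats::rnorm(1, 70, 6)
  hr <- rep(hr_base, length(grid))
  deq_feel <- rep(0, length(grid))
  post_tps <- setdiff(config$scan_timepoints, "predose")
  profile <- function(t, t0) {
    d <- pmax(0, abs(t - t0) - 30)
    exp(-d^2 / (2 * 15^2))
  }
  for (tp in post_tps) {
    imp <- latent_sess$impaired[latent_sess$timepoint == tp]
    t0 <- timepoint_minutes()[[tp]]
    if (arm == "placebo") {
      hr_amp <- 0; deq_amp <- stats::rnorm(1, 4, 2)
    } else if (isTRUE(imp)) {
      hr_amp <- stats::rnorm(1, config$hr_effect_bpm, 3)
      deq_amp <- stats::rnorm(1, config$deq_effect, 10)
    } else {
      hr_amp <- stats::rnorm(1, 4, 2)
      deq_amp <- stats::rnorm(1, 18, 8)
    }
    bump <- profile(grid, t0)
    hr <- hr + hr_amp * bump
    deq_feel <- deq_feel + deq_amp * bump
  }
  hr <- hr + stats::rnorm(length(grid), 0, 2.5)
  deq_feel <- pmin(100, pmax(0, deq_feel + stats::rnorm(length(grid), 0, 5)))
  deq_feel[1] <- pmin(100, pmax(0, stats::rnorm(1, 1, 1)))
  other <- sapply(1:4, function(i)
    pmin(100, pmax(0, deq_feel * stats::runif(1, 0.4, 0.9) +
                     stats::rnorm(length(grid), 0, 5))))
  out <- data.frame(participant = participant, session = arm,
                    time_min = grid, hr_bpm = hr, deq1 = deq_feel,
                    stringsAsFactors = FALSE)
  out[, paste0("deq", 2:5)] <- other
  out
}

# FST outcome per THC session: binary via sensitivity / false-positive rate,
# plus an ordinal 0-4 failed-component score consistent with the binary call
# (positive iff score >= 2), for ROC analysis.
simulate_fst <- function(participant, session_impaired, config) {
  p <- ifelse(session_impaired, config$fst_sensitivity,
              config$fst_false_positive_rate)
  positive <- stats::runif(length(p)) < p
  score <- integer(length(p))
  score[positive] <- 2L + stats::rbinom(sum(positive), 2, 0.6)
  score[!positive] <- stats::rbinom(sum(!positive), 1, 0.4)
  data.frame(participant = participant, session = "THC",
             session_impaired = session_impaired,
             fst_positive = positive, fst_score = score,
             stringsAsFactors = FALSE)
}

# Save/restore global RNG state so generator calls are self-contained.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
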