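#' Physiology/DEQ impairment algorithm flag
#'
#' The algorithmic half of the two-step impairment ground truth: a composite
#' z-type rule over heart-rate change and subjective intoxication. For a
#' scan at `timepoint`, `dHR` is the mean heart rate within +/- `window_min`
#' minutes of the nominal scan time minus the predose mean, and `deq_feel`
#' is the "feel drug" DEQ item nearest the scan time; the participant is
#' flagged when `dHR / sigma_hr + deq_feel / sigma_deq >= tau`.
#'
#' @param physio One session's physiology data.frame (`time_min`, `hr_bpm`,
#'   `deq1` ... as produced by [generate_cohort()]).
#' @param timepoint Scan timepoint name (`"postdose1"` etc.).
#' @param sigma_hr,sigma_deq,tau Composite-rule constants (defaults 10 bpm,
#'   30 points, 2).
#' @param window_min Half-width of the heart-rate averaging window (min).
#' @return Logical flag; attributes `"dHR"` and `"deq_feel"` carry the
#'   components.
#' @examples
#' ph <- data.frame(time_min = seq(0, 240, 20), hr_bpm = 70, deq1 = 0)
#' algorithm_flag(ph, "postdose1")
#' @export
algorithm_flag <- function(physio, timepoint, sigma_hr = 10, sigma_deq = 30,
                           tau = 2, window_min = 20) {
  t_scan <- timepoint_minutes()[[timepoint]]
  if (is.null(t_scan)) stop("unknown timepoint: ", timepoint, call. = FALSE)
  base <- physio$hr_bpm[physio$time_min <= 0]
  if (!length(base))
    stop("missing predose baseline heart-rate measurements", call. = FALSE)
  near <- abs(physio$time_min - t_scan) <= window_min
  if (!any(near))
    stop("no heart-rate measurements near scan time", call. = FALSE)
  d_hr <- mean(physio$hr_bpm[near]) - mean(base)
  deq <- physio$deq1[which.min(abs(physio$time_min - t_scan))]
  flag <- (d_hr / sigma_hr + deq / sigma_deq) >= tau
  attr(flag, "dHR") <- d_hr
  attr(flag, "deq_feel") <- deq
  flag
}

#' Conjunction impairment label
#'
#' Ground-truth impairment at a scan is the logical AND of both clinical
#' rater flags and the physiology/DEQ algorithm flag. Vectorized.
#'
#' @param rater_a,rater_b,algorithm Logical flags.
#' @return Logical: impaired if and only if all three are `TRUE`.
#' @examples
#' conjunction_label(TRUE, TRUE, TRUE)
#' conjunction_label(TRUE, FALSE, TRUE)
#' @export
conjunction_label <- function(rater_a, rater_b, algorithm) {
  as.logical(rater_a) & as.logical(rater_b) & as.logical(algorithm)
}

#' Label every scan timepoint of a cohort
#'
#' Applies [algorithm_flag()] to each (participant, session, postdose
#' timepoint), joins the two simulated rater flags, and forms the
#' conjunction label. Predose scans are always labeled not impaired. This
#' function sees only observables (physiology, DEQ, rater flags), never the
#' generator's latent state.
#'
#' @param cohort An `fnirs_cohort`.
#' @param sigma_hr,sigma_deq,tau Constants for [algorithm_flag()].
#' @return Data.frame with one row per (participant, session, timepoint):
#'   `rater_a`, `rater_b`, `algorithm`, `impaired`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_participants = 4,
#'                                      scan_types = character(0), seed = 1))
#' head(label_cohort(coh))
#' @export
label_cohort <- function(cohort, sigma_hr = 10, sigma_deq = 30, tau = 2) {
  lab <- cohort$latent[, c("participant", "session", "timepoint")]
  lab$rater_a <- NA
  lab$rater_b <- NA
  lab$algorithm <- NA
  rkey <- paste(cohort$raters$participant, cohort$raters$session,
                cohort$raters$timepoint)
  key <- paste(lab$participant, lab$session, lab$timepoint)
  m <- match(key, rkey)
  lab$rater_a <- cohort$raters$rater_a[m]
  lab$rater_b <- cohort$raters$rater_b[m]
  post <- lab$timepoint != "predose"
  for (i in which(post)) {
    ph <- cohort$physiology[cohort$physiology$participant == lab$participant[i] &
                              cohort$physiology$session == lab$session[i], ]
    lab$algorithm[i] <- as.logical(algorithm_flag(ph, lab$timepoint[i],
                                                  sigma_hr, sigma_deq, tau))
  }
  lab$impaired <- FALSE
  lab$impaired[post] <- conjunction_label(lab$rater_a[post], lab$rater_b[post],
                                          lab$algorithm[post])
  lab
}

#' Assign training classes to scans
#'
#' The impaired class comprises post-THC scans labeled impaired; every other
#' scan is nonimpaired, of one of three types: postplacebo, predose, or
#' post-THC without clear clinical impairment. Aborts when the impaired
#' class is empty (a cohort with no impaired participants cannot train the
#' classifier).
#'
#' @param labels Output of [label_cohort()].
#' @param scan_table Attended-scan table (`cohort$scan_table`, or any
#'   data.frame with `participant`, `session`, `timepoint` and `scan_id`).
#' @return `scan_table` with added logical `class_impaired` and character
#'   `nonimpaired_type` (`NA` for impaired scans); attribute
#'   `"type_counts"` tabulates the three nonimpaired types.
#' @examples
#' coh <- generate_cohort(cohort_config(n_participants = 12,
#'                                      scan_types = character(0), seed = 1))
#' \dontrun{training_class_assignment(label_cohort(coh), coh$scan_table)}
#' @export
training_class_assignment <- function(labels, scan_table) {
  key <- paste(scan_table$participant, scan_table$session, scan_table$timepoint)
  lkey <- paste(labels$participant, labels$session, labels$timepoint)
  m <- match(key, lkey)
  if (anyNA(m))
    stop("unlabeled scan(s): ", paste(scan_table$scan_id[is.na(m)][1:3],
                                      collapse = ", "), call. = FALSE)
  imp <- labels$impaired[m] & scan_table$session == "THC" &
    scan_table$timepoint != "predose"
  out <- scan_table
  out$class_impaired <- imp
  out$nonimpaired_type <- ifelse(imp, NA_character_,
    ifelse(out$timepoint == "predose", "predose",
           ifelse(out$session == "placebo", "postplacebo",
                  "post_thc_nonimpaired")))
  if (!any(imp))
    stop("impaired class is empty: no post-THC scans met the impairment ",
         "criteria; cannot train a classifier on this cohort", call. = FALSE)
  attr(out, "type_counts") <- table(out$nonimpaired_type)
  out
}
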