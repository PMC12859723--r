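#' Canonical double-gamma hemodynamic response function
#'
#' @param t Time grid in seconds.
#' @param peak Time-to-peak of the positive lobe (s).
#' @param undershoot Time-to-peak of the undershoot (s).
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @return HRF values on `t`, scaled to unit peak.
#' @examples
#' h <- double_gamma_hrf(seq(0, 30, by = 0.1))
#' @export
double_gamma_hrf <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    stats::dgamma(t, shape = undershoot, rate = 1) / ratio
  h / max(h)
}

# Band-limited Gaussian process via FFT masking, unit variance.
band_limited_noise <- function(n, sample_rate, low_hz, high_hz) {
  x <- stats::rnorm(n)
  f <- fft_freqs(n, sample_rate)
  xf <- stats::fft(x)
  keep <- abs(f) >= low_hz & abs(f) <= high_hz
  xf[!keep] <- 0
  y <- Re(stats::fft(xf, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s > 0) y <- y / s
  y
}

fft_freqs <- function(n, sample_rate) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  k * sample_rate / n
}

# 0-back/2-back alternating block regressor: 30-s blocks over the scan,
# starting with 0-back; the boxcar is "on" during 2-back blocks.
nback_boxcar <- function(n, sample_rate, block_seconds = 30) {
  t <- (seq_len(n) - 1) / sample_rate
  block <- floor(t / block_seconds)
  as.numeric(block %% 2 == 1)
}

#' Simulate per-channel hemoglobin concentration series
#'
#' Generates oxy- (HbO) and deoxyhemoglobin (HbR) concentration changes (uM)
#' for one scan. Each HbO channel is the sum of a slow drift, sinusoidal
#' physiological components (Mayer waves ~0.1 Hz, respiration ~0.25 Hz,
#' cardiac ~1.1 Hz), a task or resting-state signal term, and white noise;
#' HbR mirrors the signal term with opposite sign at ratio `hbr_ratio` plus
#' independent noise.
#'
#' For n-back scans the signal is a 30-s alternating-block boxcar convolved
#' with a double-gamma HRF; for resting scans it is a band-limited
#' (0.02-0.08 Hz) process. In both cases the signal amplitude (n-back) or
#' standard deviation (resting) is scaled by `1 + effect_size` when
#' `impaired` is `TRUE`, restricted to channels in `effect_regions` if
#' given, and impaired resting scans add a shared medial-PFC component that
#' elevates cross-channel correlation among medial channels.
#'
#' @param impaired Logical latent impairment flag for the scan.
#' @param scan_type `"resting"` or `"nback"`.
#' @param config A [cohort_config()].
#' @param montage Channel montage from [build_montage()].
#' @param amplitude Baseline signal amplitude/SD in uM.
#' @param hbr_ratio HbR-to-HbO signal ratio (default 1/3).
#' @param noise_sd White measurement noise SD in uM.
#' @return List with `hbo` and `hbr` (samples x channels matrices, uM) and
#'   the time grid `time_s`.
#' @examples
#' cfg <- cohort_config(n_participants = 4, scan_minutes = 1, seed = 1)
#' hb <- simulate_hemodynamics(FALSE, "resting", cfg)
#' dim(hb$hbo)
#' @export
simulate_hemodynamics <- function(impaired, scan_type, config,
                                  montage = build_montage(config$n_channels,
                                                          config$sd_distance_mm),
                                  amplitude = 0.4, hbr_ratio = 1 / 3,
                                  noise_sd = 0.08) {
  stopifnot(scan_type %in% c("resting", "nback"))
  n <- as.integer(round(config$sample_rate * config$scan_minutes * 60))
  fs <- config$sample_rate
  nc <- config$n_channels
  t <- (seq_len(n) - 1) / fs

  effect_ch <- if (is.null(config$effect_regions)) rep(TRUE, nc)
               else montage$region %in% config$effect_regions
  gain <- ifelse(effect_ch, 1 + config$effect_size * as.numeric(impaired), 1)

  signal_mat <- matrix(0, n, nc)
  if (scan_type == "nback") {
    box <- nback_boxcar(n, fs)
    hrf <- double_gamma_hrf(seq(0, 32, by = 1 / fs))
    reg <- stats::convolve(box, rev(hrf), type = "open")[seq_len(n)]
    reg <- reg / max(abs(reg))
    for (ch in seq_len(nc)) {
      signal_mat[, ch] <- amplitude * gain[ch] * reg *
        stats::runif(1, 0.8, 1.2)
    }
  } else {
    shared <- band_limited_noise(n, fs, 0.02, 0.08)
    medial <- band_limited_noise(n, fs, 0.02, 0.08)
    medial_ch <- montage$region == "mPFC"
    for (ch in seq_len(nc)) {
      own <- band_limited_noise(n, fs, 0.02, 0.08)
      a_base <- 0.3                                 # global shared fraction
      # impaired medial coupling scales with effect size (0.65 at the
      # default effect_size = 2) so effect_size = 0 is an exact null
      a_med <- if (impaired && medial_ch[ch])
        min(0.9, 0.325 * config$effect_size) else 0
      a_own <- sqrt(max(0, 1 - a_base^2 - a_med^2))
      signal_mat[, ch] <- amplitude * gain[ch] *
        (a_base * shared + a_med * medial + a_own * own)
    }
  }

  hbo <- matrix(0, n, nc)
  hbr <- matrix(0, n, nc)
  for (ch in seq_len(nc)) {
    drift <- stats::runif(1, -0.15, 0.15) * (t / max(t[2], max(t))) +
      0.1 * sin(2 * pi * stats::runif(1, 0.001, 0.004) * t + stats::runif(1, 0, 2 * pi))
    physio <-
      0.25 * sin(2 * pi * 0.10 * t + stats::runif(1, 0, 2 * pi)) +
      0.15 * sin(2 * pi * 0.25 * t + stats::runif(1, 0, 2 * pi)) +
      0.30 * sin(2 * pi * 1.10 * t + stats::runif(1, 0, 2 * pi))
    hbo[, ch] <- drift + physio + signal_mat[, ch] + stats::rnorm(n, sd = noise_sd)
    hbr[, ch] <- -hbr_ratio * signal_mat[, ch] + stats::rnorm(n, sd = noise_sd)
  }
  list(hbo = hbo, hbr = hbr, time_s = t)
}

#' Forward model: hemoglobin concentrations to raw detector intensities
#'
#' Applies the forward modified Beer-Lambert transform per channel and
#' wavelength, optionally injects motion artifacts (short Laplacian-amplitude
#' spikes and persistent step baseline shifts, shared across channels) in
#' optical-density space, then exponentiates around a positive baseline
#' intensity and applies multiplicative instrument noise.
#'
#' @param hbo,hbr Samples x channels concentration matrices (uM).
#' @param montage Channel montage (uses `distance_mm`).
#' @param extinction 2x2 extinction matrix from [default_extinction()]
#'   (rows = wavelengths, cols = HbO/HbR, per uM per cm).
#' @param dpf Differential pathlength factor per wavelength.
#' @param baseline Baseline detector intensity (arbitrary units); scalar or
#'   one per intensity column.
#' @param sample_rate Hz, used to size spike artifacts (< 2 s).
#' @param artifact_prob Probability that the scan receives injected motion
#'   artifacts.
#' @param instrument_noise_sd Log-scale multiplicative noise SD; 0 disables.
#' @return Samples x (2 * channels) intensity matrix with columns
#'   `ch01_w760, ch01_w850, ...`; attribute `"artifacts"` records injected
#'   spike/shift times and amplitudes.
#' @examples
#' cfg <- cohort_config(n_participants = 4, scan_minutes = 1, seed = 1)
#' hb <- simulate_hemodynamics(FALSE, "resting", cfg)
#' ii <- hb_to_intensity(hb$hbo, hb$hbr, build_montage(cfg$n_channels),
#'                       artifact_prob = 0, instrument_noise_sd = 0)
#' @export
hb_to_intensity <- function(hbo, hbr, montage,
                            extinction = default_extinction(),
                            dpf = c(6, 6), baseline = 1000,
                            sample_rate = 10,
                            artifact_prob = 0, instrument_noise_sd = 0) {
  stopifnot(is.matrix(hbo), is.matrix(hbr), all(dim(hbo) == dim(hbr)))
  if (abs(det(extinction)) < 1e-12)
    stop("singular extinction matrix: the two wavelengths do not separate HbO/HbR",
         call. = FALSE)
  n <- nrow(hbo); nc <- ncol(hbo)
  d_cm <- montage$distance_mm / 10
  wl <- rownames(extinction)
  od <- matrix(0, n, 2L * nc)
  cn <- character(2L * nc)
  for (ch in seq_len(nc)) {
    for (w in 1:2) {
      j <- 2L * (ch - 1L) + w
      od[, j] <- (extinction[w, "HbO"] * hbo[, ch] +
                  extinction[w, "HbR"] * hbr[, ch]) * d_cm[ch] * dpf[w]
      cn[j] <- sprintf("ch%02d_w%s", ch, wl[w])
    }
  }

  artifacts <- list(spikes = numeric(0), shifts = numeric(0))
  if (artifact_prob > 0 && stats::runif(1) < artifact_prob) {
    n_spike <- 1L + stats::rpois(1, 1)
    for (s in seq_len(n_spike)) {
      at <- sample.int(n, 1)
      amp <- sign(stats::rnorm(1)) * stats::rexp(1, rate = 1 / 0.05)  # Laplacian
      width <- max(2L, as.integer(stats::runif(1, 0.2, 1.8) * sample_rate))
      idx <- at:min(n, at + width - 1L)
      shape <- exp(-3 * (seq_along(idx) - 1) / length(idx))
      gains <- stats::runif(ncol(od), 0.5, 1.5)
      od[idx, ] <- od[idx, ] + outer(amp * shape, gains)
      artifacts$spikes <- c(artifacts$spikes, at)
    }
    if (stats::runif(1) < 0.5) {
      at <- sample.int(n - 1L, 1)
      amp <- sign(stats::rnorm(1)) * stats::rexp(1, rate = 1 / 0.03)
      od[(at + 1L):n, ] <- od[(at + 1L):n, ] + amp
      artifacts$shifts <- c(artifacts$shifts, at)
    }
  }

  intens <- baseline * 10^(-od)
  if (instrument_noise_sd > 0)
    intens <- intens * exp(matrix(stats::rnorm(length(intens),
                                               sd = instrument_noise_sd),
                                  nrow = n))
  colnames(intens) <- cn
  attr(intens, "artifacts") <- artifacts
  intens
}
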