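#' Preprocess a cohort and extract classifier features
#'
#' Streams every attended scan of the requested paradigm through the
#' preprocessing chain and a feature extractor, without retaining raw
#' intensities (scans are regenerated from their recorded seeds when the
#' cohort is not materialized). Scans failing quality screening are dropped
#' and reported.
#'
#' @param cohort An `fnirs_cohort`.
#' @param scan_type `"resting"` or `"nback"`.
#' @param features `"kernel"` (random-kernel transform of the concatenated
#'   HbO/HbR channels) or `"parallel"` (the 4-block parallel extraction).
#' @param bank Optional [sample_kernels()] bank for `features = "kernel"`;
#'   by default one is drawn with `n_kernels` and `seed`.
#' @param n_kernels,seed Bank parameters when `bank` is `NULL`.
#' @param band,variance_fraction Preprocessing parameters (see
#'   [preprocess_scan()]).
#' @param screen Apply channel quality screening and drop failing scans.
#' @param keep_hbo Also return the preprocessed HbO matrices (needed for
#'   [channel_importance()]); increases memory use.
#' @return List: `x` (feature matrix, rows = scans), `meta` (the
#'   corresponding `scan_table` rows), `bank` (if kernel features),
#'   `dropped` (scan ids excluded by screening), and optionally `hbo`.
#' @examples
#' cfg <- cohort_config(n_participants = 4, scan_minutes = 1,
#'                      scan_types = "resting", seed = 1)
#' coh <- generate_cohort(cfg, materialize = FALSE)
#' fx <- cohort_features(coh, n_kernels = 20)
#' dim(fx$x)
#' @export
cohort_features <- function(cohort, scan_type = "resting",
                            features = c("kernel", "parallel"),
                            bank = NULL, n_kernels = 2000, seed = 1L,
                            band = c(0.01, 0.2), variance_fraction = 0.8,
                            screen = TRUE, keep_hbo = FALSE) {
  features <- match.arg(features)
  cfg <- cohort$config
  tab <- cohort$scan_table[cohort$scan_table$scan_type == scan_type, ,
                           drop = FALSE]
  if (!nrow(tab)) stop("no attended scans of type ", scan_type, call. = FALSE)
  len <- as.integer(round(cfg$sample_rate * cfg$scan_minutes * 60))
  if (features == "kernel" && is.null(bank))
    bank <- sample_kernels(n_kernels, len, 2L * cfg$n_channels, seed = seed)
  ext <- default_extinction(cfg$wavelengths)

  rows <- list(); keep <- logical(nrow(tab)); hbo <- list()
  for (i in seq_len(nrow(tab))) {
    intens <- scan_intensity(cohort, tab$scan_id[i])
    hs <- preprocess_scan(intens, cohort$montage, cfg$sample_rate,
                          band = band, variance_fraction = variance_fraction,
                          extinction = ext, dpf = cfg$dpf, screen = screen)
    if (screen && !hs$quality$scan_pass) next
    keep[i] <- TRUE
    rows[[length(rows) + 1L]] <- if (features == "kernel")
      kernel_transform(hs, bank)
    else
      parallel_features(hs, cfg$sample_rate)
    if (keep_hbo) hbo[[length(hbo) + 1L]] <- hs$hbo
  }
  if (!length(rows))
    stop("all scans failed quality screening", call. = FALSE)
  out <- list(x = do.call(rbind, rows), meta = tab[keep, , drop = FALSE],
              bank = bank, dropped = tab$scan_id[!keep])
  if (keep_hbo) out$hbo <- hbo
  out
}
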