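#' Write a cohort to disk
#'
#' Serializes a cohort in the package's native on-disk layout: a JSON
#' manifest (`manifest.json`) describing configuration, participants,
#' latent truth, rater flags and FST outcomes; one TSV per materialized
#' scan (`scans/<scan_id>.tsv`: `time_s` then `ch01_w760 ... chNN_w850`
#' intensity columns); a physiology TSV (`physiology.tsv`: participant,
#' session, time_min, hr_bpm, deq1..deq5); and a truth TSV (`truth.tsv`:
#' participant, session, timepoint, impaired).
#'
#' @param cohort An `fnirs_cohort`.
#' @param dir Output directory (created if needed).
#' @param write_scans Write per-scan intensity TSVs (can be large).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_scans = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    config = unclass(cohort$config),
    participants = cohort$participants,
    raters = cohort$raters,
    fst = cohort$fst,
    montage = cohort$montage,
    scan_table = cohort$scan_table
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.table(cohort$physiology, file.path(dir, "physiology.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$latent, file.path(dir, "truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (write_scans && nrow(cohort$scan_table)) {
    sdir <- file.path(dir, "scans")
    dir.create(sdir, showWarnings = FALSE)
    fs <- cohort$config$sample_rate
    for (id in cohort$scan_table$scan_id) {
      m <- scan_intensity(cohort, id)
      df <- data.frame(time_s = (seq_len(nrow(m)) - 1) / fs, m,
                       check.names = FALSE)
      utils::write.table(df, file.path(sdir, paste0(id, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  invisible(dir)
}

#' Read one scan TSV
#'
#' @param path Path to a scan TSV written by [write_cohort()].
#' @return Intensity matrix (samples x columns) with the `time_s` column
#'   dropped and stored as attribute `"time_s"`.
#' @export
read_scan_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  t <- df$time_s
  m <- as.matrix(df[, setdiff(names(df), "time_s"), drop = FALSE])
  attr(m, "time_s") <- t
  m
}

#' Write impairment labels
#'
#' @param labels A [label_cohort()] data.frame.
#' @param path Output TSV path.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read impairment labels written by [write_labels()]
#' @param path TSV path.
#' @return Labels data.frame.
#' @export
read_labels <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
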