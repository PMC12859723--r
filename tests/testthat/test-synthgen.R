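test_that("cohort generation is deterministic and honors the crossover design", {
  cfg <- tiny_config(n_participants = 4, seed = 1)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$scans, b$scans)
  expect_identical(a$latent, b$latent)
  expect_identical(a$physiology, b$physiology)
  expect_identical(a$fst, b$fst)

  # placebo sessions are never latently impaired
  expect_false(any(a$latent$impaired[a$latent$session == "placebo"]))
  # predose states never impaired
  expect_false(any(a$latent$impaired[a$latent$timepoint == "predose"]))

  # full attendance: a predose and two postdose scans per session per type
  cfg2 <- tiny_config(n_participants = 3, scan_completion = 1, seed = 2)
  coh <- generate_cohort(cfg2, materialize = FALSE)
  counts <- table(coh$scan_table$participant, coh$scan_table$session)
  expect_true(all(counts == 3))  # predose + postdose1 + postdose2, resting only
})

test_that("lazy scan regeneration matches materialized intensities", {
  cfg <- tiny_config(n_participants = 3, artifact_prob = 0.5,
                     instrument_noise_sd = 0.005, seed = 9)
  mat <- generate_cohort(cfg, materialize = TRUE)
  lazy <- generate_cohort(cfg, materialize = FALSE)
  id <- mat$scan_table$scan_id[5]
  expect_identical(mat$scans[[id]], scan_intensity(lazy, id))
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(cohort_config(n_participants = 1), "n_participants")
  expect_error(cohort_config(rater_sensitivity = 1.4), "rater_sensitivity")
  expect_error(cohort_config(sample_rate = 0.013, scan_minutes = 1),
               "sample_rate")
  expect_error(cohort_config(wavelengths = c(760, -850)), "wavelengths")
  expect_error(cohort_config(effect_regions = "occipital"), "effect_regions")
})

test_that("n-back design has 12 alternating 30-second blocks in 6 minutes", {
  box <- nirsimpair:::nback_boxcar(3600, 10)
  runs <- rle(box)
  expect_equal(length(runs$lengths), 12)
  expect_true(all(runs$lengths == 300))
  expect_equal(runs$values, rep(c(0, 1), 6))
})

test_that("effect size zero makes impaired and nonimpaired generation identical", {
  cfg <- tiny_config(effect_size = 0)
  set.seed(77); a <- simulate_hemodynamics(TRUE, "resting", cfg)
  set.seed(77); b <- simulate_hemodynamics(FALSE, "resting", cfg)
  expect_identical(a, b)
  set.seed(78); a <- simulate_hemodynamics(TRUE, "nback", cfg)
  set.seed(78); b <- simulate_hemodynamics(FALSE, "nback", cfg)
  expect_identical(a, b)
})

test_that("impaired resting scans carry elevated 0.02-0.08 Hz band variance", {
  cfg <- tiny_config(effect_size = 2, scan_minutes = 2)
  band_var <- function(m, fs) {
    n <- nrow(m)
    f <- nirsimpair:::fft_freqs(n, fs)
    sel <- abs(f) >= 0.02 & abs(f) <= 0.08
    mean(apply(m, 2, function(col) {
      p <- Mod(stats::fft(col - mean(col)))^2 / n^2
      sum(p[sel])
    }))
  }
  wins <- 0
  for (s in 1:100) {
    set.seed(s);      imp <- simulate_hemodynamics(TRUE, "resting", cfg)
    set.seed(s + 1e4); non <- simulate_hemodynamics(FALSE, "resting", cfg)
    wins <- wins + (band_var(imp$hbo, 10) > band_var(non$hbo, 10))
  }
  expect_gte(wins, 95)
})

test_that("forward model round-trips through the preprocessing inverse", {
  cfg <- tiny_config()
  montage <- build_montage(4)
  set.seed(5)
  hbo <- matrix(rnorm(200 * 4, sd = 0.5), 200, 4)
  hbr <- matrix(rnorm(200 * 4, sd = 0.2), 200, 4)
  intens <- hb_to_intensity(hbo, hbr, montage, artifact_prob = 0,
                            instrument_noise_sd = 0)
  # exact round trip with the known baseline as OD reference
  od <- to_optical_density(intens, reference = rep(1000, 8))
  hb <- convert_to_hemoglobin(od, montage)
  expect_lt(max(abs(hb$hbo - hbo)), 1e-9)
  expect_lt(max(abs(hb$hbr - hbr)), 1e-9)
  # with the default temporal-mean reference, recovery is exact up to a
  # per-channel constant offset
  od2 <- to_optical_density(intens)
  hb2 <- convert_to_hemoglobin(od2, montage)
  ctr <- function(m) sweep(m, 2, colMeans(m))
  expect_lt(max(abs(ctr(hb2$hbo) - ctr(hbo))), 1e-9)
  expect_lt(max(abs(ctr(hb2$hbr) - ctr(hbr))), 1e-9)
})

test_that("zero concentrations with artifacts and noise off give constant baseline", {
  montage <- build_montage(2)
  intens <- hb_to_intensity(matrix(0, 50, 2), matrix(0, 50, 2), montage,
                            baseline = 1234, artifact_prob = 0,
                            instrument_noise_sd = 0)
  expect_true(all(intens == 1234))
})

test_that("artifact probability one injects at least one recorded spike per scan", {
  montage <- build_montage(2)
  set.seed(3)
  for (i in 1:10) {
    intens <- hb_to_intensity(matrix(0, 100, 2), matrix(0, 100, 2), montage,
                              artifact_prob = 1, instrument_noise_sd = 0)
    expect_gte(length(attr(intens, "artifacts")$spikes), 1)
  }
})

test_that("field sobriety outcomes match their sensitivity and false-positive rate", {
  cfg <- tiny_config()
  set.seed(11)
  impaired <- rep(c(TRUE, FALSE), each = 2000)
  fst <- nirsimpair:::simulate_fst(sprintf("P%04d", seq_along(impaired)),
                                   impaired, cfg)
  recall <- mean(fst$fst_positive[impaired])
  fpr <- mean(fst$fst_positive[!impaired])
  # binomial 3-SE bands around the configured 0.84 / 0.34
  expect_lt(abs(recall - 0.84), 3 * sqrt(0.84 * 0.16 / 2000))
  expect_lt(abs(fpr - 0.34), 3 * sqrt(0.34 * 0.66 / 2000))
  # ordinal 0-4 score consistent with the binary call
  expect_identical(fst$fst_positive, fst$fst_score >= 2)
  expect_true(all(fst$fst_score %in% 0:4))
})

test_that("perfect raters reproduce the latent impairment state exactly", {
  cfg <- tiny_config(n_participants = 10, rater_sensitivity = 1,
                     rater_specificity = 1, seed = 13,
                     scan_types = character(0))
  coh <- generate_cohort(cfg)
  key <- paste(coh$raters$participant, coh$raters$session, coh$raters$timepoint)
  lat <- coh$latent[coh$latent$timepoint != "predose", ]
  lkey <- paste(lat$participant, lat$session, lat$timepoint)
  m <- match(key, lkey)
  expect_identical(coh$raters$rater_a, lat$impaired[m])
  expect_identical(coh$raters$rater_b, lat$impaired[m])
})

test_that("placebo sessions show near-zero mean heart-rate change", {
  cfg <- tiny_config(n_participants = 60, scan_types = character(0), seed = 21)
  coh <- generate_cohort(cfg)
  ph <- coh$physiology[coh$physiology$session == "placebo", ]
  d_hr <- vapply(split(ph, ph$participant), function(d) {
    mean(d$hr_bpm[abs(d$time_min - 100) <= 20]) - d$hr_bpm[d$time_min == 0]
  }, numeric(1))
  expect_lt(abs(mean(d_hr)), 1.5)
})

test_that("a study-scale cohort reproduces the expected class structure", {
  cfg <- cohort_config(n_participants = 180, scan_types = "resting",
                       seed = 301)
  coh <- generate_cohort(cfg, materialize = FALSE)
  labs <- label_cohort(coh)
  cls <- training_class_assignment(labs, coh$scan_table)
  n_scans <- nrow(coh$scan_table)
  n_imp <- sum(cls$class_impaired)
  # ~893 resting scans with ~111 impaired, each within +/- 20% relative
  expect_gt(n_scans, 893 * 0.8); expect_lt(n_scans, 893 * 1.2)
  expect_gt(n_imp, 111 * 0.8);   expect_lt(n_imp, 111 * 1.2)
  # all three nonimpaired types represented
  expect_setequal(names(attr(cls, "type_counts")),
                  c("postplacebo", "predose", "post_thc_nonimpaired"))
})
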