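test_that("generate_beat_times: constant rate, modulation, reproducibility", {
  m0 <- beat_interval_model(mean_ipi = 0.75, lf_amplitude = 0,
                            hf_amplitude = 0, white_noise_sd = 0)
  bt <- generate_beat_times(m0, 30)
  expect_length(bt$beat_times, 41L)
  expect_equal(bt$beat_times[1], 0)
  expect_equal(bt$ipis, rep(0.75, 40), tolerance = 1e-12)
  expect_equal(diff(bt$beat_times), bt$ipis)

  # pure HF modulation: mean -> mean_ipi, oscillation follows the closed form
  mh <- beat_interval_model(mean_ipi = 0.75, lf_amplitude = 0,
                            hf_amplitude = 0.05, hf_freq = 0.25,
                            white_noise_sd = 0)
  bh <- generate_beat_times(mh, 300)
  expect_equal(mean(bh$ipis), 0.75, tolerance = 0.002)
  pred <- 0.75 + 0.05 * sin(2 * pi * 0.25 * bh$beat_times[-length(bh$beat_times)])
  expect_equal(bh$ipis, pred, tolerance = 1e-12)
  # oscillation period ~ 4 s: successive zero upcrossings of (ipi - mean)
  dev <- bh$ipis - 0.75
  ups <- which(dev[-1] > 0 & dev[-length(dev)] <= 0)
  periods <- diff(bh$beat_times[ups])
  expect_true(all(abs(periods - 4) < 0.8))

  # reproducible bit-for-bit under a fixed seed
  ms <- beat_interval_model(white_noise_sd = 0.02, seed = 99)
  expect_identical(generate_beat_times(ms, 120), generate_beat_times(ms, 120))

  expect_error(generate_beat_times(m0, 0), "positive")
  expect_error(generate_beat_times(m0, -5), "positive")
})

test_that("render_ppg: trough placement, linearity, detachment runs", {
  fx <- clean_recording(duration = 30)
  s <- fx$recording$samples
  expect_length(s, 30 * 32)
  # interior local minima count = number of inter-pulse gaps
  mins <- which(diff(sign(diff(s))) > 0) + 1L
  expect_equal(length(mins), length(fx$beat_times) - 2L)
  # each minimum within one sample of a beat time
  tmins <- (mins - 1) / 32
  inner <- fx$beat_times[-c(1, length(fx$beat_times))]
  expect_lt(max(vapply(inner, function(b) min(abs(tmins - b)), 0)),
            1 / 32 + 1e-9)

  # amplitude linearity of the clean signal
  r1 <- render_ppg(fx$beat_times, fs = 32, duration = 30, amplitude_scale = 1)
  r5 <- render_ppg(fx$beat_times, fs = 32, duration = 30, amplitude_scale = 0.5)
  expect_equal(r5$samples, 0.5 * r1$samples, tolerance = 1e-12)

  # detachment: constant runs of the configured duration appear
  art <- artifact_spec(motion_burst_rate = 0, detachment_rate = 600,
                       detachment_duration = 5)
  rd <- render_ppg(fx$beat_times, fs = 32, duration = 30, artifacts = art,
                   seed = 4)
  runs <- rle(rd$samples)
  expect_gte(max(runs$lengths), 5 * 32)

  expect_error(render_ppg(c(1, 1, 2), fs = 32), "strictly increasing")
  expect_error(render_ppg(c(0, 1), fs = 8), "at least 16")
})

test_that("generate_cohort: truth table, day-0 count, structure, errors", {
  eff <- list(day_effect(0), day_effect(1, hr_shift = 10))
  coh <- generate_cohort(n_participants = 10, day_effects = eff,
                         day0_fraction = 1, recording_duration = 330,
                         artifacts = NULL, missingness = NULL,
                         days = c(0, 1), seed = 5)
  tr <- coh$truth
  hr0 <- tr$true_hr[tr$day == 0][order(tr$participant_id[tr$day == 0])]
  hr1 <- tr$true_hr[tr$day == 1][order(tr$participant_id[tr$day == 1])]
  expect_equal(mean(hr1) - mean(hr0), 10, tolerance = 1e-12)

  # exactly 8 of 61 carry a day-0 recording under the default fraction
  coh61 <- generate_cohort(n_participants = 61, recording_duration = 330,
                           artifacts = NULL, days = 0, seed = 7)
  expect_equal(sum(coh61$manifest$day == 0), 8L)

  expect_error(generate_cohort(n_participants = 1), "at least 2")
  expect_error(generate_cohort(day_effects = list()), "non-empty")
  expect_error(generate_cohort(day_effects = list(day_effect(1), day_effect(1))),
               "unique")

  # reproducibility of the full cohort object
  a <- generate_cohort(n_participants = 3, recording_duration = 330,
                       days = 2, seed = 3)
  b <- generate_cohort(n_participants = 3, recording_duration = 330,
                       days = 2, seed = 3)
  expect_identical(a$recordings, b$recordings)
})

test_that("cohort day effects propagate to extracted features in expectation", {
  # hf_scale < 1 strictly decreases extracted RMSSD and HF over seeds
  n_seeds <- 20
  drop <- matrix(NA_real_, n_seeds, 2)
  for (s in seq_len(n_seeds)) {
    full <- modulated_recording(duration = 120, seed = s, hf_amplitude = 0.025)
    half <- modulated_recording(duration = 120, seed = s, hf_amplitude = 0.0125)
    hf_full <- hrv_features(ipi_series(full$recording))
    hf_half <- hrv_features(ipi_series(half$recording))
    drop[s, ] <- c(hf_full$rmssd_ms - hf_half$rmssd_ms,
                   hf_full$hf_ms2 - hf_half$hf_ms2)
  }
  # the stated property is a decrease in expectation; individual short
  # segments can buck the trend through extraction variability
  expect_gt(mean(drop[, 1]), 0)
  expect_gt(mean(drop[, 2]), 0)
  expect_gt(mean(drop[, 1] > 0), 0.5)
  expect_gt(mean(drop[, 2] > 0), 0.5)
})

test_that("ground-truth and extracted IPIs agree on clean renderings", {
  fx <- clean_recording(mean_ipi = 0.8, duration = 120)
  ip <- ipi_series(fx$recording)
  # align by nearest trough to each beat
  expect_equal(60 / mean(ip$clean_ipis), 60 / 0.8, tolerance = 0.5 / 60 * 80)
  # per-interval agreement within 1/fs
  gt <- fx$ipis
  matched <- vapply(seq_along(ip$raw_ipis), function(i) {
    min(abs(gt - ip$raw_ipis[i]))
  }, 0)
  expect_lt(max(matched), 1 / 32 + 1e-9)
})

test_that("cohort tree round-trips through CSV", {
  coh <- generate_cohort(n_participants = 2, recording_duration = 330,
                         days = c(0, 1), day0_fraction = 1,
                         missingness = NULL, artifacts = NULL, seed = 2)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  man <- read_manifest(file.path(dir, "manifest.csv"))
  expect_setequal(man$file, paste0(names(coh$recordings), ".csv"))
  rec <- read_recording(file.path(dir, man$file[1]))
  orig <- coh$recordings[[sub("\\.csv$", "", man$file[1])]]
  expect_equal(rec$samples, orig$samples, tolerance = 1e-9)
  expect_equal(rec$fs, orig$fs, tolerance = 1e-9)
  expect_equal(rec$start_time, orig$start_time, tolerance = 1e-9)
})
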