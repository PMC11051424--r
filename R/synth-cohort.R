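#' Day-wise effect applied to a synthetic cohort
#'
#' Encodes the three phenomena the analysis is designed to detect after a
#' corticosteroid course: a heart-rate shift, suppression of high-frequency
#' (parasympathetically mediated) interval variability, and attenuation of the
#' pulse amplitude (vasoconstriction). Values are configuration, not constants:
#' a null cohort uses `hr_shift = 0, hf_scale = 1, amplitude_scale = 1`
#' everywhere.
#'
#' @param day_index study day, 0 to 4 (0 = pre-injection, 1..4 = 24..96 h after
#'   the first injection).
#' @param hr_shift additive heart-rate shift in bpm (signed).
#' @param hf_scale multiplies the HF modulation amplitude (>= 0).
#' @param amplitude_scale multiplies the rendered pulse amplitude (> 0).
#' @export
day_effect <- function(day_index, hr_shift = 0, hf_scale = 1,
                       amplitude_scale = 1) {
  stopifnot_scalar(day_index, "day_index", lower = 0, upper = 4)
  stopifnot_scalar(hf_scale, "hf_scale", lower = 0)
  stopifnot_scalar(amplitude_scale, "amplitude_scale", lower = 1e-12)
  structure(list(day_index = as.integer(day_index), hr_shift = hr_shift,
                 hf_scale = hf_scale, amplitude_scale = amplitude_scale),
            class = "day_effect")
}

#' @describeIn day_effect a null design over all five study days.
#' @export
null_day_effects <- function() lapply(0:4, day_effect)

#' @describeIn day_effect a design mimicking the reported post-betamethasone
#'   pattern: about +10 bpm and halved HF variability 24 h after the first
#'   injection, recovering over days 2-3, with pulse amplitude shrinking
#'   steadily from day 0 to day 4.
#' @export
reference_day_effects <- function() list(
  day_effect(0, hr_shift = 0, hf_scale = 1, amplitude_scale = 1.00),
  day_effect(1, hr_shift = 10, hf_scale = 0.5, amplitude_scale = 0.90),
  day_effect(2, hr_shift = 5, hf_scale = 0.7, amplitude_scale = 0.85),
  day_effect(3, hr_shift = -2, hf_scale = 1.1, amplitude_scale = 0.80),
  day_effect(4, hr_shift = 0, hf_scale = 1.0, amplitude_scale = 0.75)
)

.HOUR <- 3600
.DAY <- 86400

# default structured missingness: four designated participants each miss one
# post-injection day, reproducing a 57-complete / 61 paired structure when the
# participant lacking day 4 also lacks day 0.
.default_missingness <- function(n) {
  if (n < 12L) return(list())
  list(`9` = 1L, `10` = 2L, `11` = 3L, `12` = 4L)
}

#' Generate a synthetic multi-day PPG cohort with known ground truth
#'
#' Simulates the five-day measurement schedule around a two-injection
#' corticosteroid course: each participant receives injection 1 at a random
#' clock time and injection 2 exactly 24 h later; recordings are laid down
#' around the day-wise measurement targets (1 h before injection 1 for day 0;
#' 24/48/72/96 h after it for days 1-4, the day-1 recording ending at
#' injection 2). Per-participant physiology (baseline heart rate, LF/HF
#' modulation, pulse shape) is drawn once per participant; day effects are
#' applied on top of it and recorded in a ground-truth table.
#'
#' Only a configurable fraction of participants carries a day-0 (pre-injection)
#' recording, emulating the clinical reality that most women have already
#' received their first injection when monitoring starts.
#'
#' @param n_participants number of participants (>= 2); 61 matches the study
#'   design the generator emulates.
#' @param day_effects list of [day_effect()] objects, one per simulated day,
#'   unique day indices in 0..4. Must be non-empty.
#' @param day0_fraction fraction of participants with a day-0 recording
#'   (default 8/61); the count is `round(n_participants * day0_fraction)`.
#' @param recording_duration length of each per-day recording, seconds
#'   (default 1200 s; must exceed 300 s plus scheduling slack).
#' @param fs sampling rate, Hz.
#' @param artifacts an [artifact_spec()] applied to every recording, or `NULL`
#'   for clean signals.
#' @param noise_sd always-on sensor noise (PPG units).
#' @param missingness `"default"` for the structured 57-complete pattern,
#'   `NULL`/empty list for none, or a named list mapping participant index to
#'   the day indices to drop.
#' @param day_hr_sd within-participant day-to-day heart-rate variation, bpm
#'   (default 3): real repeated measurements differ between days through
#'   circadian phase, posture and state even without any drug effect.
#' @param day_mod_sd log-scale day-to-day jitter on the LF/HF modulation
#'   amplitudes (default 0.15).
#' @param day_amp_sd log-scale day-to-day jitter on the pulse amplitude
#'   (default 0.10), emulating contact/posture changes between days.
#' @param days optional integer subset of day indices to actually simulate
#'   (useful to skip unused days in large simulations); defaults to all days
#'   in `day_effects`.
#' @param seed root seed; all participant- and day-level draws derive from it.
#' @return an object of class `ppg_cohort`: list with `participants`,
#'   `manifest`, `truth` data frames and a named list `recordings` of
#'   [ppg_recording()] objects (each carrying its ground-truth beat times as
#'   attribute `"beat_times"`, on the absolute study clock).
#' @export
generate_cohort <- function(n_participants = 61,
                            day_effects = null_day_effects(),
                            day0_fraction = 8 / 61,
                            recording_duration = 1200,
                            fs = 32,
                            artifacts = artifact_spec(),
                            noise_sd = 0.02,
                            missingness = "default",
                            days = NULL,
                            day_hr_sd = 3,
                            day_mod_sd = 0.15,
                            day_amp_sd = 0.10,
                            seed = 1L) {
  if (n_participants < 2) stop("`n_participants` must be at least 2", call. = FALSE)
  if (length(day_effects) == 0L) stop("`day_effects` must be non-empty", call. = FALSE)
  eff_days <- vapply(day_effects, function(e) e$day_index, integer(1))
  if (anyDuplicated(eff_days) || any(eff_days < 0 | eff_days > 4)) {
    stop("day indices in `day_effects` must be unique and within 0..4", call. = FALSE)
  }
  effects <- stats::setNames(day_effects, eff_days)
  if (is.null(days)) days <- sort(eff_days)
  days <- sort(intersect(days, eff_days))
  if (recording_duration < 310) stop("`recording_duration` must be >= 310 s", call. = FALSE)

  n <- as.integer(n_participants)
  miss <- if (identical(missingness, "default")) .default_missingness(n)
          else if (is.null(missingness)) list() else missingness

  # participant-level draws
  pid <- sprintf("P%02d", seq_len(n))
  base <- with_seed(derive_seed(seed, "participants"), {
    data.frame(
      participant_id = pid,
      base_hr = pmin(pmax(stats::rnorm(n, 85, 7), 65), 105),
      lf_amplitude = 0.015 * exp(stats::rnorm(n, 0, 0.2)),
      hf_amplitude = 0.025 * exp(stats::rnorm(n, 0, 0.2)),
      lf_freq = stats::runif(n, 0.07, 0.12),
      hf_freq = stats::runif(n, 0.20, 0.30),
      white_noise_sd = 0.01,
      pulse_amp = exp(stats::rnorm(n, 0, 0.15)),
      systolic_width = 0.09 * exp(stats::rnorm(n, 0, 0.08)),
      diastolic_delay = 0.25 * exp(stats::rnorm(n, 0, 0.08)),
      injection1_time = round(stats::runif(n, 8, 20)) * .HOUR,
      stringsAsFactors = FALSE
    )
  })
  base$injection2_time <- base$injection1_time + .DAY

  # who carries a day-0 recording (exactly round(n * day0_fraction) of them)
  k0 <- round(n * day0_fraction)
  eligible0 <- setdiff(seq_len(n), as.integer(names(miss)))
  if (k0 > length(eligible0)) eligible0 <- seq_len(n)
  day0_ids <- sort(with_seed(derive_seed(seed, "day0"),
                             sample(eligible0, min(k0, length(eligible0)))))

  recordings <- list()
  manifest <- list()
  truth <- list()
  for (i in seq_len(n)) {
    t1 <- base$injection1_time[i]
    t2 <- base$injection2_time[i]
    dropped <- miss[[as.character(i)]]
    for (d in days) {
      if (d == 0L && !(i %in% day0_ids)) next
      if (d %in% dropped) next
      eff <- effects[[as.character(d)]]
      jit <- with_seed(derive_seed(seed, pid[i], d, "dayjitter"), {
        list(hr = stats::rnorm(1, 0, day_hr_sd),
             lf = exp(stats::rnorm(1, 0, day_mod_sd)),
             hf = exp(stats::rnorm(1, 0, day_mod_sd)),
             amp = exp(stats::rnorm(1, 0, day_amp_sd)))
      })
      hr_day <- base$base_hr[i] + eff$hr_shift + jit$hr
      model <- beat_interval_model(
        mean_ipi = 60 / hr_day,
        lf_amplitude = base$lf_amplitude[i] * jit$lf,
        lf_freq = base$lf_freq[i],
        hf_amplitude = base$hf_amplitude[i] * eff$hf_scale * jit$hf,
        hf_freq = base$hf_freq[i],
        white_noise_sd = base$white_noise_sd[i],
        seed = derive_seed(seed, pid[i], d, "beats")
      )
      target <- if (d == 0L) t1 - .HOUR else t1 + d * .DAY
      # day 1 must end by injection 2; day 0 is placed so that a window
      # starting exactly at the target (1 h before injection 1) fits
      rec_start <- if (d == 1L) t2 - recording_duration
                   else if (d == 0L) target - (recording_duration - 300) / 2
                   else target - recording_duration / 2
      beats <- generate_beat_times(model, recording_duration)
      # pulse time-scale tracks the beat interval so that successive pulses
      # do not swallow each other's diastolic limb at high heart rates
      sc <- (60 / hr_day) / 0.75
      tpl <- pulse_template(
        systolic_amplitude = base$pulse_amp[i],
        systolic_width = base$systolic_width[i] * sc,
        diastolic_amplitude = 0.35 * base$pulse_amp[i],
        diastolic_delay = base$diastolic_delay[i] * sc,
        diastolic_width = 0.12 * sc
      )
      rec <- render_ppg(beats$beat_times, tpl, fs = fs,
                        duration = recording_duration,
                        artifacts = artifacts,
                        amplitude_scale = eff$amplitude_scale * jit$amp,
                        noise_sd = noise_sd,
                        seed = derive_seed(seed, pid[i], d, "render"),
                        start_time = rec_start,
                        events = c(injection1 = t1, injection2 = t2))
      attr(rec, "beat_times") <- rec_start + beats$beat_times
      key <- sprintf("%s_d%d", pid[i], d)
      recordings[[key]] <- rec
      manifest[[key]] <- data.frame(
        participant_id = pid[i], day = d,
        file = paste0(key, ".csv"),
        start_time = rec_start,
        injection1_time = t1, injection2_time = t2,
        stringsAsFactors = FALSE)
      truth[[key]] <- data.frame(
        participant_id = pid[i], day = d,
        true_hr = base$base_hr[i] + eff$hr_shift,
        realized_hr = hr_day, realized_mean_ipi = 60 / hr_day,
        hr_shift = eff$hr_shift, hf_scale = eff$hf_scale,
        amplitude_scale = eff$amplitude_scale,
        hf_amplitude = base$hf_amplitude[i] * eff$hf_scale,
        stringsAsFactors = FALSE)
    }
  }
  structure(
    list(participants = base,
         manifest = do.call(rbind, c(manifest, list(make.row.names = FALSE))),
         truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
         recordings = recordings,
         day_effects = day_effects,
         seed = seed),
    class = "ppg_cohort"
  )
}

#' @export
print.ppg_cohort <- function(x, ...) {
  cat(sprintf("<ppg_cohort> %d participants, %d recordings over days {%s}\n",
              nrow(x$participants), length(x$recordings),
              paste(sort(unique(x$manifest$day)), collapse = ",")))
  invisible(x)
}

#' Write a synthetic cohort to a directory tree of CSV files
#'
#' Produces one `time_s, ppg` CSV per participant-day, a `manifest.csv`
#' (participant_id, day, file, start_time, injection1_time, injection2_time)
#' and a `ground_truth.csv` with the injected per-day effects. All files are
#' RFC-4180 CSV with a header row.
#'
#' @param cohort a `ppg_cohort` from [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ppg_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(cohort$recordings)) {
    write_recording(cohort$recordings[[key]],
                    file.path(dir, paste0(key, ".csv")))
  }
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}
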