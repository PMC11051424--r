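#' Artifact specification for the synthetic renderer
#'
#' Wrist PPG suffers from two dominant failure modes: broadband motion bursts
#' while the wearer moves, and flat stretches while the sensor is detached.
#' Both are emulated structurally; the rates are illustrative defaults, not
#' estimates of any particular cohort's artifact burden.
#'
#' @param motion_burst_rate expected motion bursts per minute (>= 0).
#' @param motion_burst_sd standard deviation of the additive broadband noise
#'   within a burst, in PPG units.
#' @param motion_burst_duration duration of one burst, seconds.
#' @param detachment_rate expected sensor detachments per hour (>= 0).
#' @param detachment_duration duration of one detachment, seconds; the signal
#'   is constant over the gap.
#' @return an object of class `artifact_spec`.
#' @export
artifact_spec <- function(motion_burst_rate = 0.2,
                          motion_burst_sd = 0.5,
                          motion_burst_duration = 2,
                          detachment_rate = 1,
                          detachment_duration = 10) {
  stopifnot_scalar(motion_burst_rate, "motion_burst_rate", lower = 0)
  stopifnot_scalar(motion_burst_sd, "motion_burst_sd", lower = 0)
  stopifnot_scalar(motion_burst_duration, "motion_burst_duration", lower = 0)
  stopifnot_scalar(detachment_rate, "detachment_rate", lower = 0)
  stopifnot_scalar(detachment_duration, "detachment_duration", lower = 0)
  structure(
    list(motion_burst_rate = motion_burst_rate,
         motion_burst_sd = motion_burst_sd,
         motion_burst_duration = motion_burst_duration,
         detachment_rate = detachment_rate,
         detachment_duration = detachment_duration),
    class = "artifact_spec"
  )
}

#' Construct a PPG recording object
#'
#' @param samples numeric vector of PPG values (arbitrary units).
#' @param fs sampling frequency in Hz (> 0).
#' @param start_time recording start as seconds on an absolute study clock.
#' @param events named numeric vector of event times on the same clock
#'   (e.g. `injection1`, `injection2`); may be empty.
#' @return an object of class `ppg_recording`.
#' @export
ppg_recording <- function(samples, fs, start_time = 0, events = numeric(0)) {
  if (!is.numeric(samples) || length(samples) == 0L) {
    stop("`samples` must be a non-empty numeric vector", call. = FALSE)
  }
  stopifnot_scalar(fs, "fs", lower = 1e-9)
  structure(
    list(samples = as.numeric(samples), fs = fs,
         start_time = start_time, events = events),
    class = "ppg_recording"
  )
}

#' @export
print.ppg_recording <- function(x, ...) {
  cat(sprintf("<ppg_recording> %d samples @ %g Hz (%.1f s), start %.1f s, %d event(s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              x$start_time, length(x$events)))
  invisible(x)
}

# time axis of a recording on the absolute clock
recording_times <- function(rec) {
  rec$start_time + (seq_along(rec$samples) - 1L) / rec$fs
}

#' Render a PPG signal from beat times and a pulse template
#'
#' Each beat contributes one causal template pulse by superposition. Because
#' the template vanishes before its onset and the preceding pulse's tail is
#' decaying, the local minima of the clean signal fall on the beat onsets,
#' which is what trough-based interval extraction assumes.
#'
#' @param beat_times strictly increasing beat onset times in seconds
#'   (relative to the recording start).
#' @param template a [pulse_template()].
#' @param fs sampling frequency, Hz (>= 16; wrist devices commonly use 32).
#' @param duration recording length in seconds; defaults to the last beat time.
#' @param artifacts an [artifact_spec()] or `NULL` for a clean rendering.
#' @param amplitude_scale multiplies the pulse amplitudes (vasoconstriction
#'   knob for day-wise effects).
#' @param noise_sd standard deviation of always-on sensor noise (PPG units);
#'   0 gives the analytically clean signal.
#' @param seed seed for artifact placement and sensor noise.
#' @param start_time,events passed to [ppg_recording()].
#' @return a [ppg_recording()] whose length is `ceiling(duration * fs)` samples.
#' @export
render_ppg <- function(beat_times, template = pulse_template(), fs = 32,
                       duration = NULL, artifacts = NULL,
                       amplitude_scale = 1, noise_sd = 0, seed = 1L,
                       start_time = 0, events = numeric(0)) {
  stopifnot(inherits(template, "pulse_template"))
  if (fs < 16) stop("`fs` must be at least 16 Hz", call. = FALSE)
  if (length(beat_times) < 1L || is.unsorted(beat_times, strictly = TRUE)) {
    stop("`beat_times` must be non-empty and strictly increasing", call. = FALSE)
  }
  stopifnot_scalar(amplitude_scale, "amplitude_scale", lower = 1e-12)
  if (is.null(duration)) duration <- max(beat_times)
  support <- .template_support(template)
  p <- .template_params(template)
  bulk_width <- max(p$t_dia + 2 * template$diastolic_width,
                    p$t_shoulder + 2 * p$s_shoulder)
  if (length(beat_times) > 1L && bulk_width > mean(diff(beat_times))) {
    warning("pulse template is wider than the mean beat interval; ",
            "pulses overlap (rendering proceeds by superposition)")
  }
  n <- as.integer(ceiling(duration * fs))
  w <- as.integer(ceiling(support * fs)) + 1L
  sig <- numeric(n + w + 1L)  # padded; trimmed below

  # per beat: add the template over its support window, vectorised per beat
  offs <- 0:(w - 1L)
  for (b in beat_times) {
    i0 <- floor(b * fs) + 1L  # sample index at/just before onset
    idx <- i0 + offs
    tau <- (idx - 1L) / fs - b
    sig[idx] <- sig[idx] + eval_pulse(template, tau)
  }
  sig <- sig[seq_len(n)] * amplitude_scale

  with_seed(seed, {
    if (noise_sd > 0) sig <- sig + stats::rnorm(n, 0, noise_sd)
    if (!is.null(artifacts)) {
      stopifnot(inherits(artifacts, "artifact_spec"))
      dur_s <- n / fs
      n_motion <- stats::rpois(1, artifacts$motion_burst_rate * dur_s / 60)
      if (n_motion > 0 && artifacts$motion_burst_sd > 0) {
        starts <- stats::runif(n_motion, 0, dur_s)
        for (s in starts) {
          i1 <- max(1L, floor(s * fs) + 1L)
          i2 <- min(n, i1 + as.integer(artifacts$motion_burst_duration * fs))
          sig[i1:i2] <- sig[i1:i2] +
            stats::rnorm(i2 - i1 + 1L, 0, artifacts$motion_burst_sd)
        }
      }
      n_det <- stats::rpois(1, artifacts$detachment_rate * dur_s / 3600)
      if (n_det > 0 && artifacts$detachment_duration > 0) {
        starts <- stats::runif(n_det, 0, dur_s)
        for (s in starts) {
          i1 <- max(1L, floor(s * fs) + 1L)
          i2 <- min(n, i1 + as.integer(artifacts$detachment_duration * fs))
          sig[i1:i2] <- sig[max(i1 - 1L, 1L)]
        }
      }
    }
  })
  ppg_recording(sig, fs, start_time = start_time, events = events)
}
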