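#' Beat-interval model with low- and high-frequency modulation
#'
#' Inter-pulse intervals are generated as a mean interval plus sinusoidal
#' low-frequency (LF, 0.04-0.15 Hz, baroreflex-like) and high-frequency
#' (HF, 0.15-0.40 Hz, respiratory sinus arrhythmia-like) modulation plus white
#' noise, in the spirit of integral-pulse-frequency-modulation generators.
#' Band powers of the ground-truth interval series are therefore known in
#' closed form (a sinusoid of amplitude `a` carries power `a^2 / 2`).
#'
#' @param mean_ipi mean inter-pulse interval in seconds, in \[0.4, 2.0\].
#' @param lf_amplitude,lf_freq amplitude (s) and frequency (Hz, in 0.04-0.15)
#'   of the low-frequency modulation.
#' @param hf_amplitude,hf_freq amplitude (s) and frequency (Hz, in 0.15-0.40)
#'   of the high-frequency modulation.
#' @param white_noise_sd standard deviation (s) of additive white noise per
#'   interval.
#' @param seed integer seed making the generated series reproducible.
#' @return an object of class `beat_interval_model`.
#' @export
beat_interval_model <- function(mean_ipi = 0.75,
                                lf_amplitude = 0.015, lf_freq = 0.095,
                                hf_amplitude = 0.025, hf_freq = 0.25,
                                white_noise_sd = 0.01,
                                seed = 1L) {
  stopifnot_scalar(mean_ipi, "mean_ipi", lower = 0.4, upper = 2.0)
  stopifnot_scalar(lf_amplitude, "lf_amplitude", lower = 0)
  stopifnot_scalar(hf_amplitude, "hf_amplitude", lower = 0)
  stopifnot_scalar(white_noise_sd, "white_noise_sd", lower = 0)
  if (lf_amplitude > 0) stopifnot_scalar(lf_freq, "lf_freq", lower = 0.04, upper = 0.15)
  if (hf_amplitude > 0) stopifnot_scalar(hf_freq, "hf_freq", lower = 0.15, upper = 0.40)
  structure(
    list(mean_ipi = mean_ipi,
         lf_amplitude = lf_amplitude, lf_freq = lf_freq,
         hf_amplitude = hf_amplitude, hf_freq = hf_freq,
         white_noise_sd = white_noise_sd,
         seed = as.integer(seed)),
    class = "beat_interval_model"
  )
}

#' Generate beat times and ground-truth inter-pulse intervals
#'
#' Beats start at t = 0 and accumulate: the k-th interval is evaluated from the
#' modulation at the time of the beat that opens it. Intervals are floored at
#' 0.05 s so the series stays strictly positive even under extreme noise.
#'
#' @param model a [beat_interval_model()].
#' @param duration recording duration in seconds (> 0); the last beat is the
#'   last one at or before `duration`.
#' @return a list with `beat_times` (first element 0) and `ipis`
#'   (`diff(beat_times)`, the ground-truth interval series).
#' @examples
#' bt <- generate_beat_times(beat_interval_model(white_noise_sd = 0), 30)
#' @export
generate_beat_times <- function(model, duration) {
  stopifnot(inherits(model, "beat_interval_model"))
  if (!is.numeric(duration) || length(duration) != 1L || is.na(duration) ||
      duration <= 0) {
    stop("`duration` must be a single positive number of seconds", call. = FALSE)
  }
  n_max <- ceiling(duration / max(model$mean_ipi -
                                    model$lf_amplitude - model$hf_amplitude -
                                    4 * model$white_noise_sd, 0.05)) + 8L
  noise <- if (model$white_noise_sd > 0) {
    with_seed(model$seed, stats::rnorm(n_max, 0, model$white_noise_sd))
  } else {
    numeric(n_max)
  }
  times <- numeric(n_max + 1L)
  t <- 0
  k <- 1L
  while (t <= duration && k <= n_max) {
    ipi <- model$mean_ipi +
      model$lf_amplitude * sin(2 * pi * model$lf_freq * t) +
      model$hf_amplitude * sin(2 * pi * model$hf_freq * t) +
      noise[k]
    ipi <- max(ipi, 0.05)
    t <- t + ipi
    k <- k + 1L
    times[k] <- t
  }
  beat_times <- times[seq_len(k)]
  beat_times <- beat_times[beat_times <= duration + 1e-12]
  list(beat_times = beat_times, ipis = diff(beat_times))
}
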