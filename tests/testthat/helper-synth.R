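# Shared fixtures built in code at test time.

# constant-rate clean rendering with known beat times
clean_recording <- function(mean_ipi = 0.75, duration = 60, fs = 32,
                            template = pulse_template()) {
  bt <- generate_beat_times(
    beat_interval_model(mean_ipi = mean_ipi, lf_amplitude = 0,
                        hf_amplitude = 0, white_noise_sd = 0), duration)
  rec <- render_ppg(bt$beat_times, template, fs = fs, duration = duration)
  attr(rec, "beat_times") <- bt$beat_times
  list(recording = rec, beat_times = bt$beat_times, ipis = bt$ipis)
}

# physiological modulated rendering
modulated_recording <- function(duration = 300, seed = 1, noise_sd = 0.02,
                                hf_amplitude = 0.025, mean_ipi = 0.75) {
  m <- beat_interval_model(mean_ipi = mean_ipi, lf_amplitude = 0.015,
                           lf_freq = 0.1, hf_amplitude = hf_amplitude,
                           hf_freq = 0.25, white_noise_sd = 0.01, seed = seed)
  bt <- generate_beat_times(m, duration)
  rec <- render_ppg(bt$beat_times, fs = 32, duration = duration,
                    noise_sd = noise_sd, seed = seed + 1000)
  attr(rec, "beat_times") <- bt$beat_times
  list(recording = rec, beat_times = bt$beat_times, ipis = bt$ipis)
}

# one pulse of the analytic template sampled at fs
template_pulse <- function(template = pulse_template(), ipi = 0.75, fs = 32) {
  tau <- seq(0, ipi, by = 1 / fs)
  eval_pulse(template, tau)
}
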