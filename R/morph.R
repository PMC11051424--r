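#' Segment a recording into per-beat pulse spans
#'
#' One span per consecutive trough pair; spans whose inter-pulse interval was
#' rejected by the artifact rules are excluded, so morphology is only computed
#' on beats the IPI pipeline trusts.
#'
#' @param recording a [ppg_recording()].
#' @param ipis the recording's `ipi_series`.
#' @return data frame with sample indices `i1`, `i2` (inclusive, into
#'   `recording$samples`), one row per accepted pulse; zero rows when nothing
#'   is accepted.
#' @export
segment_pulses <- function(recording, ipis) {
  stopifnot(inherits(recording, "ppg_recording"), inherits(ipis, "ipi_series"))
  if (length(ipis$trough_times) < 2L) {
    return(data.frame(i1 = integer(0), i2 = integer(0)))
  }
  idx <- as.integer(round((ipis$trough_times - recording$start_time) *
                            recording$fs)) + 1L
  keep <- which(ipis$valid_mask)
  data.frame(i1 = idx[keep], i2 = idx[keep + 1L])
}

# 3-point moving average with quadratic edge padding, so the smoothing bias
# is uniform across the whole pulse (an unsmoothed endpoint next to smoothed
# neighbours would corrupt the one-sided derivative stencils there)
.smooth3 <- function(y) {
  n <- length(y)
  if (n < 3L) return(y)
  y0 <- 3 * y[1] - 3 * y[2] + y[3]
  y1 <- 3 * y[n] - 3 * y[n - 1] + y[n - 2]
  yp <- c(y0, y, y1)
  (yp[-c(1, 2)] + yp[-c(1, n + 2)] + yp[-c(n + 1, n + 2)]) / 3
}

.cdiff <- function(y, fs) {
  n <- length(y)
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) * fs / 2
  # second-order one-sided estimates at the ends
  d[1] <- (-3 * y[1] + 4 * y[2] - y[3]) * fs / 2
  d[n] <- (3 * y[n] - 4 * y[n - 1] + y[n - 2]) * fs / 2
  d
}

# indices of strict interior local maxima / minima
.local_max <- function(v) which(v[-c(1, 2)] < v[-c(1, length(v))] &
                                  v[-c(length(v) - 1, length(v))] <= v[-c(1, length(v))]) + 1L
.local_min <- function(v) .local_max(-v)

#' Locate waveform and derivative fiducial points on one pulse
#'
#' Works on the samples of a single pulse (initial trough IT to final trough
#' FT). The signal is smoothed with a 3-point moving average before central
#' differencing: second-derivative fiducials at wearable sampling rates are
#' noise-sensitive. Fiducials: SP is the global interior maximum; a1 the
#' maximum of the first derivative on the rising limb; b1 the first local
#' minimum of the first derivative after a1; a2 the first local maximum of
#' the second derivative after IT; b2 the global minimum of the second
#' derivative between a2 and 25% of the pulse duration past SP; e2 the
#' highest local maximum of the second derivative after b2 and before 80% of
#' the pulse duration. `complete` is `FALSE` whenever any point cannot be
#' located, and such pulses are excluded from feature aggregation.
#'
#' @param pulse numeric vector of PPG samples spanning one beat (>= 8).
#' @param fs sampling rate, Hz.
#' @return list with integer sample indices `it, sp, ft, a1, b1, a2, b2, e2`,
#'   the end-diastolic velocity `edv` (first derivative at FT), the smoothed
#'   signal `sm` and derivative traces `d1`, `d2`, and `complete`.
#' @export
locate_fiducials <- function(pulse, fs) {
  n <- length(pulse)
  res <- list(it = 1L, sp = NA_integer_, ft = n, a1 = NA_integer_,
              b1 = NA_integer_, a2 = NA_integer_, b2 = NA_integer_,
              e2 = NA_integer_, edv = NA_real_, sm = NULL, d1 = NULL,
              d2 = NULL, complete = FALSE)
  if (n < 8L) return(res)
  sm <- .smooth3(pulse)
  d1 <- .cdiff(sm, fs)
  d2 <- .cdiff(d1, fs)
  res$sm <- sm; res$d1 <- d1; res$d2 <- d2
  res$edv <- d1[n]

  interior <- 2:(n - 1)
  sp <- interior[which.max(sm[interior])]
  if (!(sm[sp] >= sm[sp - 1] && sm[sp] >= sm[sp + 1] &&
        sm[sp] > sm[1] && sm[sp] > sm[n])) {
    return(res)
  }
  res$sp <- sp
  if (sp <= 2L) return(res)
  rise <- 2:(sp - 1)
  res$a1 <- rise[which.max(d1[rise])]

  b1_cand <- .local_min(d1)
  b1_cand <- b1_cand[b1_cand > res$a1]
  if (length(b1_cand)) res$b1 <- b1_cand[1]

  a2_cand <- .local_max(d2)
  a2_cand <- a2_cand[a2_cand > 1L]
  if (length(a2_cand)) res$a2 <- a2_cand[1]

  if (!is.na(res$a2)) {
    hi <- min(n, sp + as.integer(round(0.25 * (n - 1))))
    if (hi > res$a2 + 1L) {
      rng <- (res$a2 + 1L):hi
      res$b2 <- rng[which.min(d2[rng])]
    }
  }
  if (!is.na(res$b2)) {
    hi <- as.integer(round(0.8 * (n - 1))) + 1L
    e2_cand <- .local_max(d2)
    e2_cand <- e2_cand[e2_cand > res$b2 & e2_cand <= hi]
    if (length(e2_cand)) res$e2 <- e2_cand[which.max(d2[e2_cand])]
  }
  res$complete <- !anyNA(c(res$sp, res$a1, res$b1, res$a2, res$b2, res$e2))
  res
}

# sub-sample level-crossing time (in samples, 1-based) on segment i1..i2 of y:
# first upward crossing of `level` when direction = "up" (scanning forward),
# first downward crossing when "down"
.crossing <- function(y, i1, i2, level, direction = c("up", "down")) {
  direction <- match.arg(direction)
  for (i in i1:(i2 - 1L)) {
    if (direction == "up" && y[i] < level && y[i + 1L] >= level) {
      return(i + (level - y[i]) / (y[i + 1L] - y[i]))
    }
    if (direction == "down" && y[i] >= level && y[i + 1L] < level) {
      return(i + (y[i] - level) / (y[i] - y[i + 1L]))
    }
  }
  NA_real_
}

#' Compute the morphology feature set for one pulse
#'
#' Implements the full catalogue of amplitude, time, area, velocity/
#' acceleration, ratio, slope and angle features. Widths at X% are measured
#' at `IT + X% of the pulse amplitude`: systolic width runs from the rising
#' crossing to SP, diastolic width from SP to the falling crossing, both with
#' sub-sample interpolation; the reported ratio is diastolic/systolic. Areas
#' are trapezoidal, above the straight IT-FT baseline, so slow drift does not
#' leak into them. Angles use amplitude normalised to the pulse amplitude and
#' time in seconds, reported in degrees. `b2_amplitude` is the absolute value
#' of the second derivative at b2; the b2/a2 ratio uses that absolute value
#' while e2/a2 is signed.
#'
#' @param pulse numeric vector of one pulse's samples.
#' @param fid fiducials from [locate_fiducials()] (must be `complete`).
#' @param fs sampling rate, Hz.
#' @return one-row data frame with 35 feature columns, or all-`NA` when the
#'   fiducials are incomplete.
#' @export
pulse_features <- function(pulse, fid, fs) {
  as.data.frame(as.list(.pulse_feature_values(pulse, fid, fs)))
}

.morph_feature_names <- c(
  "pwa", "b2_amplitude", "pwd", "spd", "dpd", "t_a1", "t_a1b1",
  "t_a2b2", "t_b2e2", "auc_total", "auc1", "auc2", "mean_v",
  "idr_v", "mean_acc", "msv", "sfv", "dw10_sw10", "dw25_sw25",
  "dw50_sw50", "dw60_sw60", "t_s_pwd", "t_a1_pwd", "t_a1b1_pwd",
  "t_a2b2_pwd", "t_b2e2_pwd", "b2_a2", "e2_a2", "spd_pwd",
  "sp_spd", "pulsatility_index", "slope_it_sp", "slope_sp_ft",
  "angle_alpha", "angle_gamma")

# fast path: named numeric vector of the 35 features
.pulse_feature_values <- function(pulse, fid, fs) {
  na_row <- stats::setNames(rep(NA_real_, length(.morph_feature_names)),
                            .morph_feature_names)
  if (!isTRUE(fid$complete)) return(na_row)
  y <- pulse
  n <- length(y)
  t <- (seq_len(n) - 1L) / fs
  it <- fid$it; sp <- fid$sp; ft <- fid$ft
  d1 <- fid$d1; d2 <- fid$d2

  pwa <- y[sp] - y[it]
  pwd <- t[ft] - t[it]
  spd <- t[sp] - t[it]
  dpd <- t[ft] - t[sp]
  if (pwa <= 0 || pwd <= 0) return(na_row)

  # areas above the IT-FT baseline (trapezoid); SP ordinate shared
  base <- y[it] + (y[ft] - y[it]) * (t - t[it]) / pwd
  z <- y - base
  auc1 <- trapz(t[it:sp], z[it:sp])
  auc2 <- trapz(t[sp:ft], z[sp:ft])

  width_ratio <- function(frac) {
    level <- y[it] + frac * pwa
    cs <- .crossing(y, it, sp, level, "up")
    cd <- .crossing(y, sp, ft, level, "down")
    if (is.na(cs) || is.na(cd)) return(NA_real_)
    swidth <- (sp - cs) / fs
    dwidth <- (cd - sp) / fs
    if (swidth <= 0) return(NA_real_)
    dwidth / swidth
  }

  mean_v <- mean(d1)
  q <- stats::quantile(d1, c(0.1, 0.9), names = FALSE)
  c(
    pwa = pwa,
    b2_amplitude = abs(d2[fid$b2]),
    pwd = pwd, spd = spd, dpd = dpd,
    t_a1 = t[fid$a1] - t[it],
    t_a1b1 = t[fid$b1] - t[fid$a1],
    t_a2b2 = t[fid$b2] - t[fid$a2],
    t_b2e2 = t[fid$e2] - t[fid$b2],
    auc_total = auc1 + auc2, auc1 = auc1, auc2 = auc2,
    mean_v = mean_v,
    idr_v = q[2] - q[1],
    mean_acc = mean(d2),
    msv = d1[fid$a1],
    sfv = d1[it],
    dw10_sw10 = width_ratio(0.10),
    dw25_sw25 = width_ratio(0.25),
    dw50_sw50 = width_ratio(0.50),
    dw60_sw60 = width_ratio(0.60),
    t_s_pwd = (t[sp] - t[fid$a1]) / pwd,
    t_a1_pwd = (t[fid$a1] - t[it]) / pwd,
    t_a1b1_pwd = (t[fid$b1] - t[fid$a1]) / pwd,
    t_a2b2_pwd = (t[fid$b2] - t[fid$a2]) / pwd,
    t_b2e2_pwd = (t[fid$e2] - t[fid$b2]) / pwd,
    b2_a2 = if (d2[fid$a2] != 0) abs(d2[fid$b2]) / d2[fid$a2] else NA_real_,
    e2_a2 = if (d2[fid$a2] != 0) d2[fid$e2] / d2[fid$a2] else NA_real_,
    spd_pwd = spd / pwd,
    sp_spd = y[sp] / spd,
    pulsatility_index = if (mean_v != 0) (d1[fid$a1] - fid$edv) / mean_v
                        else NA_real_,
    slope_it_sp = (y[sp] - y[it]) / spd,
    slope_sp_ft = (y[ft] - y[sp]) / dpd,
    angle_alpha = atan2((y[sp] - y[it]) / pwa, spd) * 180 / pi,
    angle_gamma = atan2((y[ft] - y[sp]) / pwa, dpd) * 180 / pi
  )
}

#' Aggregate per-pulse morphology features to segment level
#'
#' The per-feature median over accepted pulses: robust to the occasional
#' distorted pulse, and consistent with the non-parametric reporting style of
#' the downstream statistics.
#'
#' @param per_pulse data frame of per-pulse features ([pulse_features()] rows).
#' @return one-row data frame of medians plus `n_pulses_used`.
#' @export
aggregate_segment <- function(per_pulse) {
  if (nrow(per_pulse) == 0L) {
    stop("no complete pulses: segment has no morphology features", call. = FALSE)
  }
  out <- as.data.frame(lapply(per_pulse, stats::median, na.rm = TRUE))
  out$n_pulses_used <- nrow(per_pulse)
  out
}

#' Per-day ensemble-average pulse
#'
#' Each pulse is resampled onto a common 100-point grid over its own IT-FT
#' span (relative time 0-1 of the pulse duration) and averaged. Amplitudes
#' are deliberately not normalised: day-to-day amplitude attenuation must be
#' visible in the ensemble.
#'
#' @param pulses list of numeric vectors, one accepted pulse each.
#' @param day_index study day label carried through to the result.
#' @param n_grid number of grid points.
#' @return list with `day_index`, `n_pulses`, `grid` (0-1) and `mean` (the
#'   ensemble waveform).
#' @export
ensemble_average <- function(pulses, day_index = NA_integer_, n_grid = 100L) {
  if (length(pulses) == 0L) stop("no pulses to average", call. = FALSE)
  grid <- seq(0, 1, length.out = n_grid)
  m <- vapply(pulses, function(p) {
    stats::approx(seq(0, 1, length.out = length(p)), p, xout = grid)$y
  }, numeric(n_grid))
  list(day_index = day_index, n_pulses = length(pulses), grid = grid,
       mean = rowMeans(m))
}

#' Segment-level morphology features for one recording
#'
#' Segments the accepted beats, locates fiducials on each pulse, computes the
#' per-pulse feature catalogue and aggregates to the segment median.
#'
#' @param recording a [ppg_recording()].
#' @param ipis the matching `ipi_series`.
#' @return list with `features` (one-row data frame incl. `n_pulses_used`),
#'   `pulses` (list of accepted complete pulse sample vectors, for ensemble
#'   averaging) and `n_excluded` (pulses dropped for incomplete fiducials).
#'   `features` is `NULL` when no pulse is complete.
#' @export
morph_features <- function(recording, ipis) {
  spans <- segment_pulses(recording, ipis)
  fs <- recording$fs
  rows <- list()
  pulses <- list()
  n_excl <- 0L
  for (j in seq_len(nrow(spans))) {
    p <- recording$samples[spans$i1[j]:spans$i2[j]]
    fid <- locate_fiducials(p, fs)
    if (isTRUE(fid$complete)) {
      rows[[length(rows) + 1L]] <- .pulse_feature_values(p, fid, fs)
      pulses[[length(pulses) + 1L]] <- p
    } else {
      n_excl <- n_excl + 1L
    }
  }
  if (length(rows) == 0L) {
    return(list(features = NULL, pulses = list(), n_excluded = n_excl))
  }
  per_pulse <- as.data.frame(do.call(rbind, rows))
  list(features = aggregate_segment(per_pulse),
       pulses = pulses, n_excluded = n_excl)
}
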