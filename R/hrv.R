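#' Time-domain HR and HRV features
#'
#' Heart rate is the mean interval converted to beats per minute. SDNN is the
#' sample (n-1) standard deviation of the intervals. RMSSD and pNN50 are
#' computed over successive differences of intervals that are adjacent in the
#' original beat sequence: differences across a rejected interval are not
#' physiological successions and are excluded via `pair_ok`.
#'
#' @param ipis clean inter-pulse intervals, seconds.
#' @param pair_ok optional logical vector of length `length(ipis) - 1`;
#'   `TRUE` where intervals i and i+1 were adjacent beats. Defaults to all.
#' @return list with `hr` (bpm), `sdnn` (ms), `rmssd` (ms), `pnn50` (%).
#'   Features whose minimum sample size is not met are `NA`, not zero.
#' @export
time_domain <- function(ipis, pair_ok = NULL) {
  n <- length(ipis)
  if (n < 2L) return(list(hr = NA_real_, sdnn = NA_real_,
                          rmssd = NA_real_, pnn50 = NA_real_))
  ms <- ipis * 1000
  hr <- 60 / mean(ipis)
  sdnn <- stats::sd(ms)
  if (is.null(pair_ok)) pair_ok <- rep(TRUE, n - 1L)
  d <- diff(ms)[pair_ok]
  if (n < 3L || length(d) == 0L) {
    return(list(hr = hr, sdnn = sdnn, rmssd = NA_real_, pnn50 = NA_real_))
  }
  list(hr = hr, sdnn = sdnn,
       rmssd = sqrt(mean(d^2)),
       pnn50 = 100 * mean(abs(d) > 50))
}

#' Frequency-domain HRV features from the interpolated interval series
#'
#' The gap-filled interval tachogram is resampled to a uniform grid by cubic
#' spline, linearly detrended, and its spectrum estimated by Welch averaging
#' (120-s Hann-windowed segments, 50% overlap). Band powers are integrals of
#' the one-sided spectral density: LF 0.04-0.15 Hz, HF 0.15-0.40 Hz, total
#' power 0.003-0.40 Hz. Units are ms^2.
#'
#' @param interpolated_ipis gap-filled intervals, seconds (`NA` at
#'   non-interpolated edges is tolerated and dropped).
#' @param trough_times trough times, length `length(interpolated_ipis) + 1`.
#' @param fs_resample tachogram resampling rate, Hz.
#' @param seg_len_s Welch segment length, seconds.
#' @param bands list with `tp`, `lf`, `hf` two-element band edges, Hz.
#' @return list with `tp`, `lf`, `hf` (ms^2) and `lf_hf`; `lf_hf` is `NA`
#'   when the HF power is zero.
#' @export
frequency_domain <- function(interpolated_ipis, trough_times,
                             fs_resample = 4, seg_len_s = 120,
                             bands = list(tp = c(0.003, 0.40),
                                          lf = c(0.04, 0.15),
                                          hf = c(0.15, 0.40))) {
  x <- trough_times[-length(trough_times)]
  y <- interpolated_ipis * 1000
  ok <- !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(y) < 16L || diff(range(x)) < 4 * 1 / min(bands$lf[1], 0.04)) {
    return(list(tp = NA_real_, lf = NA_real_, hf = NA_real_, lf_hf = NA_real_))
  }
  grid <- seq(min(x), max(x), by = 1 / fs_resample)
  u <- stats::spline(x, y, xout = grid, method = "natural")$y
  u <- stats::lm.fit(cbind(1, seq_along(u)), u)$residuals

  w <- welch_psd(u, fs = fs_resample, seg_len = round(seg_len_s * fs_resample))
  band_power <- function(b) sum(w$psd[w$freq > b[1] & w$freq <= b[2]]) * w$df
  tp <- band_power(bands$tp)
  lf <- band_power(bands$lf)
  hf <- band_power(bands$hf)
  list(tp = tp, lf = lf, hf = hf,
       lf_hf = if (hf > 0) lf / hf else NA_real_)
}

#' Welch power spectral density estimate
#'
#' Hann-windowed, mean-removed, 50%-overlapping segments; one-sided density
#' scaled so that `sum(psd) * df` equals the signal variance for a long
#' stationary signal.
#'
#' @param x numeric signal, uniformly sampled.
#' @param fs sampling rate, Hz.
#' @param seg_len segment length in samples (clipped to `length(x)`).
#' @param overlap fractional overlap between segments.
#' @return list with `freq`, `psd`, `df`.
#' @export
welch_psd <- function(x, fs, seg_len = length(x), overlap = 0.5) {
  n <- length(x)
  L <- min(seg_len, n)
  step <- max(1L, floor(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1))
  U <- sum(w^2)
  nf <- floor(L / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(nf)]
    acc <- acc + (Mod(X)^2) / (fs * U)
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist for even L)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (L %% 2 == 0) dbl[nf] <- 1
  psd <- psd * dbl
  list(freq = (seq_len(nf) - 1L) * fs / L, psd = psd, df = fs / L)
}

#' Poincare-plot descriptors SD1 and SD2
#'
#' SD1 (short-term variability) is the dispersion perpendicular to the
#' identity line of the lag-1 scatter plot, `sqrt(var(diff)/2)`; SD2 follows
#' from the identity `sd1^2 + sd2^2 = 2 * sdnn^2`. Successive differences use
#' the same adjacency rule as RMSSD.
#'
#' @inheritParams time_domain
#' @return list with `sd1` (ms), `sd2` (ms), `sd1_sd2` (`NA` when SD2 = 0).
#' @export
poincare <- function(ipis, pair_ok = NULL) {
  n <- length(ipis)
  if (n < 3L) return(list(sd1 = NA_real_, sd2 = NA_real_, sd1_sd2 = NA_real_))
  ms <- ipis * 1000
  if (is.null(pair_ok)) pair_ok <- rep(TRUE, n - 1L)
  d <- diff(ms)[pair_ok]
  if (length(d) < 2L) return(list(sd1 = NA_real_, sd2 = NA_real_,
                                  sd1_sd2 = NA_real_))
  half_vd <- stats::var(d) / 2
  sd1 <- sqrt(half_vd)
  sd2sq <- 2 * stats::var(ms) - half_vd
  sd2 <- sqrt(max(sd2sq, 0))
  list(sd1 = sd1, sd2 = sd2,
       sd1_sd2 = if (sd2 > 0) sd1 / sd2 else NA_real_)
}

#' Sample entropy of an interval series
#'
#' `-log(A / B)` where `B` counts pairs of length-`m` templates within
#' Chebyshev distance `r` of each other (self-matches excluded) and `A` the
#' same for length `m + 1`. The tolerance is `r_factor` times the standard
#' deviation of the series. A zero-variance series returns 0 by convention
#' (the tolerance would be zero and the match probability is otherwise
#' degenerate); fewer than `min_n` intervals, or `B = 0`, give `NA`.
#'
#' @param ipis interval series (any constant units).
#' @param m template length.
#' @param r_factor tolerance as a multiple of the series SD.
#' @param min_n minimum series length.
#' @return sample entropy (unitless), possibly `Inf` when no template match
#'   survives extension.
#' @export
sample_entropy <- function(ipis, m = 2L, r_factor = 0.2, min_n = 50L) {
  n <- length(ipis)
  if (n < min_n) return(NA_real_)
  s <- stats::sd(ipis)
  if (s == 0) return(0)
  r <- r_factor * s
  nt <- n - m  # templates 1..n-m exist at both lengths m and m+1
  if (nt < 2L) return(NA_real_)
  cheb <- matrix(0, nt, nt)
  for (k in 0:(m - 1L)) {
    seg <- ipis[(1L + k):(nt + k)]
    cheb <- pmax(cheb, abs(outer(seg, seg, "-")))
  }
  B <- (sum(cheb <= r) - nt) / 2
  if (B == 0) return(NA_real_)
  seg <- ipis[(1L + m):(nt + m)]
  cheb <- pmax(cheb, abs(outer(seg, seg, "-")))
  A <- (sum(cheb <= r) - nt) / 2
  -log(A / B)
}

#' Short-term detrended fluctuation analysis exponent (alpha 1)
#'
#' The mean-centred interval series is integrated; for each box size `n` in
#' `min_box:max_box` the profile is split into non-overlapping boxes, each
#' box is least-squares detrended with a first-order polynomial, and `F(n)`
#' is the root-mean-square residual. Alpha 1 is the least-squares slope of
#' `log F(n)` versus `log n`, capturing interval correlations over 4-16
#' heartbeats.
#'
#' @param ipis interval series (interpolated/gap-filled; `NA` dropped).
#' @param min_box,max_box box-size range in beats.
#' @param min_n minimum series length.
#' @return the scaling exponent, or `NA` when any box size yields fewer than
#'   two boxes or the series is too short or constant.
#' @export
dfa_alpha1 <- function(ipis, min_box = 4L, max_box = 16L, min_n = 100L) {
  x <- ipis[!is.na(ipis)]
  n <- length(x)
  if (n < min_n || stats::sd(x) == 0) return(NA_real_)
  prof <- cumsum(x - mean(x))
  sizes <- min_box:max_box
  Fn <- numeric(length(sizes))
  for (j in seq_along(sizes)) {
    nb <- sizes[j]
    k <- n %/% nb
    if (k < 2L) return(NA_real_)
    m <- matrix(prof[seq_len(nb * k)], nrow = nb)
    t <- seq_len(nb)
    tc <- t - mean(t)
    colm <- colMeans(m)
    slope <- as.numeric(crossprod(tc, m)) / sum(tc^2)
    resid <- m - outer(tc, slope) - matrix(colm, nb, k, byrow = TRUE)
    Fn[j] <- sqrt(mean(resid^2))
  }
  if (any(Fn <= 0)) return(NA_real_)
  lx <- log(sizes); ly <- log(Fn)
  sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
}

#' All 13 HR/HRV features for one segment
#'
#' @param ipis an `ipi_series` from [ipi_series()].
#' @param fs_resample,seg_len_s spectral settings forwarded to
#'   [frequency_domain()].
#' @return one-row data frame with columns `hr_bpm, sdnn_ms, rmssd_ms,
#'   pnn50_pct, tp_ms2, lf_ms2, hf_ms2, lf_hf, sd1_ms, sd2_ms, sd1_sd2,
#'   sampen, dfa_alpha1`.
#' @export
hrv_features <- function(ipis, fs_resample = 4, seg_len_s = 120) {
  stopifnot(inherits(ipis, "ipi_series"))
  # a clean pair is a physiological succession iff the two valid intervals
  # were consecutive in the raw series
  idx <- which(ipis$valid_mask)
  pair_ok <- if (length(idx) > 1L) diff(idx) == 1L else logical(0)
  td <- time_domain(ipis$clean_ipis, pair_ok)
  fd <- frequency_domain(ipis$interpolated_ipis, ipis$trough_times,
                         fs_resample = fs_resample, seg_len_s = seg_len_s)
  pc <- poincare(ipis$clean_ipis, pair_ok)
  se <- sample_entropy(ipis$clean_ipis)
  a1 <- dfa_alpha1(ipis$interpolated_ipis)
  data.frame(hr_bpm = td$hr, sdnn_ms = td$sdnn, rmssd_ms = td$rmssd,
             pnn50_pct = td$pnn50, tp_ms2 = fd$tp, lf_ms2 = fd$lf,
             hf_ms2 = fd$hf, lf_hf = fd$lf_hf, sd1_ms = pc$sd1,
             sd2_ms = pc$sd2, sd1_sd2 = pc$sd1_sd2, sampen = se,
             dfa_alpha1 = a1)
}
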