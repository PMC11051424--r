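#' Detect PPG waveform troughs
#'
#' Native trough detector: the signal is band-passed (0.5-8 Hz, zero phase),
#' local minima are taken where the derivative changes sign, gated by an
#' adaptive amplitude criterion (minimum must sit in the lower part of the
#' local pulse amplitude, and the local amplitude must be a substantial
#' fraction of the recording's robust amplitude, which silences flat
#' detachment stretches), and thinned by a 0.4-s refractory period that keeps
#' the deeper of two competing minima. Each surviving trough is refined to the
#' local minimum of the lightly smoothed raw signal.
#'
#' @param recording a [ppg_recording()], at least 10 s long, `fs >= 16` Hz.
#' @param low,high band-pass corner frequencies, Hz.
#' @param refractory minimum spacing between troughs, s.
#' @param depth_frac required trough depth as a fraction of the local pulse
#'   amplitude.
#' @param min_local_amp minimum local amplitude as a fraction of the robust
#'   global amplitude for a region to be considered signal rather than a
#'   detached-sensor stretch.
#' @return numeric vector of trough times on the study clock (possibly empty
#'   for a flat signal), strictly increasing.
#' @export
detect_troughs <- function(recording, low = 0.5, high = 8,
                           refractory = 0.4, depth_frac = 0.25,
                           min_local_amp = 0.25) {
  stopifnot(inherits(recording, "ppg_recording"))
  x <- recording$samples
  fs <- recording$fs
  if (fs < 16) stop("`fs` must be at least 16 Hz", call. = FALSE)
  if (length(x) < 10 * fs) stop("recording must be at least 10 s", call. = FALSE)
  if (stats::sd(x) < 1e-12) {
    ppg_log("flat signal: no troughs detected")
    return(numeric(0))
  }
  bp <- bandpass_zerophase(x, fs, low, high)

  # block-wise local amplitude envelope (2-s blocks, interpolated per sample)
  blk <- as.integer(2 * fs)
  nb <- max(1L, length(bp) %/% blk)
  idx_blk <- pmin(rep(seq_len(nb), each = blk, length.out = length(bp)), nb)
  amp_blk <- tapply(bp, idx_blk, function(v) diff(range(v)))
  amp_global <- stats::quantile(amp_blk, 0.75, names = FALSE)
  local_amp <- amp_blk[idx_blk]

  d <- diff(bp)
  cand <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1L
  keepable <- bp[cand] < -depth_frac * local_amp[cand] &
    local_amp[cand] > min_local_amp * amp_global
  cand <- cand[keepable]
  if (length(cand) == 0L) {
    ppg_log("no troughs passed the amplitude gate")
    return(numeric(0))
  }

  # refractory thinning, keeping the deeper competitor
  min_gap <- as.integer(round(refractory * fs))
  kept <- integer(length(cand))
  nk <- 0L
  for (i in cand) {
    if (nk > 0L && i - kept[nk] < min_gap) {
      if (bp[i] < bp[kept[nk]]) kept[nk] <- i
    } else {
      nk <- nk + 1L
      kept[nk] <- i
    }
  }
  kept <- kept[seq_len(nk)]

  # refine against the lightly smoothed raw signal
  sm <- stats::filter(x, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- x[is.na(sm)]
  half <- 3L
  refined <- vapply(kept, function(i) {
    lo <- max(1L, i - half); hi <- min(length(x), i + half)
    lo + which.min(sm[lo:hi]) - 1L
  }, integer(1))
  refined <- unique(refined)
  recording$start_time + (refined - 1L) / fs
}

#' Apply the physiological-range and successive-difference IPI rejection rules
#'
#' An interval is invalid when it lies outside 0.4-2.0 s, or when it differs
#' from its preceding interval by more than 20%. "Preceding interval" defaults
#' to the nearest preceding *valid* interval, which stops a single outlier
#' from cascading rejections; the first interval (and any interval with no
#' valid predecessor yet) is judged on the physiological range alone.
#'
#' @param raw_ipis numeric vector of raw inter-pulse intervals, seconds.
#' @param range physiological range, seconds.
#' @param rel_tol maximum relative difference from the preceding interval.
#' @param predecessor `"last-valid"` (default) or `"raw"` (compare to the
#'   immediately preceding interval regardless of its validity).
#' @return logical vector, `TRUE` where the interval is kept.
#' @export
reject_ipis <- function(raw_ipis, range = c(0.4, 2.0), rel_tol = 0.20,
                        predecessor = c("last-valid", "raw")) {
  if (length(raw_ipis) == 0L) stop("`raw_ipis` must be non-empty", call. = FALSE)
  predecessor <- match.arg(predecessor)
  n <- length(raw_ipis)
  valid <- logical(n)
  prev <- NA_real_
  for (i in seq_len(n)) {
    ok <- raw_ipis[i] >= range[1] && raw_ipis[i] <= range[2]
    ref <- if (predecessor == "raw" && i > 1L) raw_ipis[i - 1L] else prev
    if (ok && !is.na(ref) && abs(raw_ipis[i] - ref) / ref > rel_tol) ok <- FALSE
    valid[i] <- ok
    if (predecessor == "last-valid") {
      if (ok) prev <- raw_ipis[i]
    } else {
      prev <- raw_ipis[i]
    }
  }
  valid
}

#' Fill rejected IPIs by natural cubic spline interpolation
#'
#' The spline is fitted through the valid (trough time, interval) pairs and
#' evaluated at the trough times of the rejected intervals. Rejected intervals
#' before the first or after the last valid interval are not extrapolated and
#' come back as `NA`.
#'
#' @param trough_times trough times, length `length(raw_ipis) + 1`.
#' @param raw_ipis raw intervals, seconds.
#' @param valid_mask logical mask from [reject_ipis()].
#' @return numeric vector, same length as `raw_ipis`: valid entries unchanged,
#'   interior invalid entries spline-filled (floored at 0.05 s), edge invalid
#'   entries `NA`.
#' @export
interpolate_ipis <- function(trough_times, raw_ipis, valid_mask) {
  stopifnot(length(trough_times) == length(raw_ipis) + 1L,
            length(valid_mask) == length(raw_ipis))
  if (sum(valid_mask) < 4L) {
    stop("fewer than 4 valid IPIs: segment unusable for interpolation",
         call. = FALSE)
  }
  x <- trough_times[-length(trough_times)]
  out <- raw_ipis
  inv <- which(!valid_mask)
  if (length(inv)) {
    vi <- which(valid_mask)
    interior <- inv[inv > min(vi) & inv < max(vi)]
    edge <- setdiff(inv, interior)
    if (length(interior)) {
      out[interior] <- pmax(
        stats::spline(x[vi], raw_ipis[vi], xout = x[interior],
                      method = "natural")$y,
        0.05)
    }
    out[edge] <- NA_real_
  }
  out
}

#' Extract the full inter-pulse-interval series from a recording
#'
#' Runs trough detection, forms raw IPIs, applies the rejection rules and the
#' spline gap filling, and computes the discarded fraction used by the
#' segment-quality gate. The discarded fraction is gap-aware: an invalid
#' interval much longer than the typical beat (e.g. bridging a detached
#' stretch, or an undetected run of beats) counts as the number of beats it
#' swallowed, and uncovered time at the segment edges is charged the same way.
#' On series with no such long gaps this reduces exactly to
#' `1 - n_valid / n_raw`.
#'
#' @param recording a [ppg_recording()].
#' @param ... passed to [detect_troughs()].
#' @param predecessor,rel_tol passed to [reject_ipis()].
#' @return an object of class `ipi_series`: list with `trough_times`,
#'   `raw_ipis`, `valid_mask`, `clean_ipis`, `interpolated_ipis`,
#'   `discarded_fraction`, `fs`.
#' @export
ipi_series <- function(recording, predecessor = "last-valid", rel_tol = 0.20,
                       ...) {
  troughs <- detect_troughs(recording, ...)
  dur <- length(recording$samples) / recording$fs
  if (length(troughs) < 5L) {
    return(structure(
      list(trough_times = troughs, raw_ipis = numeric(0),
           valid_mask = logical(0), clean_ipis = numeric(0),
           interpolated_ipis = numeric(0), discarded_fraction = 1,
           fs = recording$fs),
      class = "ipi_series"))
  }
  raw <- diff(troughs)
  valid <- reject_ipis(raw, rel_tol = rel_tol, predecessor = predecessor)
  interp <- if (sum(valid) >= 4L) {
    interpolate_ipis(troughs, raw, valid)
  } else {
    ifelse(valid, raw, NA_real_)
  }

  typical <- stats::median(raw[valid & raw >= 0.4 & raw <= 2.0])
  if (!is.finite(typical)) typical <- stats::median(raw)
  mult <- ifelse(!valid & raw > 2.0, pmax(1, round(raw / typical)), 1)
  edge_deficit <- floor((troughs[1] - recording$start_time) / typical) +
    floor((recording$start_time + dur - troughs[length(troughs)]) / typical)
  denom <- sum(mult) + max(edge_deficit, 0)
  discarded <- 1 - sum(valid) / denom

  structure(
    list(trough_times = troughs, raw_ipis = raw, valid_mask = valid,
         clean_ipis = raw[valid], interpolated_ipis = interp,
         discarded_fraction = discarded, fs = recording$fs),
    class = "ipi_series")
}

#' @export
print.ipi_series <- function(x, ...) {
  cat(sprintf("<ipi_series> %d intervals, %.1f%% discarded, mean IPI %.3f s\n",
              length(x$raw_ipis), 100 * x$discarded_fraction,
              mean(x$clean_ipis)))
  invisible(x)
}

#' Write an IPI series to CSV
#'
#' Columns: trough_time_s, ipi_s, valid, ipi_interpolated_s (one row per
#' interval, stamped with the trough opening it).
#'
#' @param ipis an `ipi_series`.
#' @param path output CSV path.
#' @export
write_ipi_series <- function(ipis, path) {
  stopifnot(inherits(ipis, "ipi_series"))
  utils::write.csv(
    data.frame(trough_time_s = ipis$trough_times[-length(ipis$trough_times)],
               ipi_s = ipis$raw_ipis,
               valid = ipis$valid_mask,
               ipi_interpolated_s = ipis$interpolated_ipis),
    path, row.names = FALSE)
  invisible(path)
}
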