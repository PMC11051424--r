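#' Candidate 5-minute analysis windows around a daily target time
#'
#' Enumerates window start times on a regular grid inside the tolerance band
#' around the target measurement time (24/48/72/96 h after the first injection,
#' +/- 4 h by default; 1 h before the first injection for day 0), clipped to
#' the recording span and, when given, to a hard cap such as the next
#' injection time (day-0 and day-1 measurements must precede the first and
#' second injections respectively). Candidates are ordered by distance to the
#' target; ties break toward the earlier start so selection is deterministic.
#'
#' @param recording a [ppg_recording()] with `start_time` on the study clock.
#' @param target_time desired window start on the study clock, seconds.
#' @param tolerance half-width of the allowed band, seconds (>= 0).
#' @param duration window length, seconds (the analysis uses 300 s).
#' @param cap_time optional latest permitted window END on the study clock.
#' @param step grid spacing between successive candidate starts, seconds.
#' @return numeric vector of candidate start times (possibly empty), ordered
#'   by `abs(start - target_time)`.
#' @export
candidate_windows <- function(recording, target_time, tolerance = 4 * 3600,
                              duration = 300, cap_time = NULL, step = 30) {
  stopifnot(inherits(recording, "ppg_recording"))
  stopifnot_scalar(tolerance, "tolerance", lower = 0)
  rec_start <- recording$start_time
  rec_end <- rec_start + length(recording$samples) / recording$fs
  lo <- max(target_time - tolerance, rec_start)
  # the whole window must fit in the tolerance band, except that a zero (or
  # sub-window) tolerance still admits the window starting at the target
  hi <- min(target_time + max(tolerance - duration, 0), rec_end - duration)
  if (!is.null(cap_time)) hi <- min(hi, cap_time - duration)
  if (hi < lo) return(numeric(0))
  # grid anchored on the target so that, when reachable, the target itself
  # is a candidate
  k <- seq(ceiling((lo - target_time) / step - 1e-9),
           floor((hi - target_time) / step + 1e-9))
  starts <- target_time + k * step
  if (length(starts) == 0L) starts <- min(max(target_time, lo), hi)
  starts[order(abs(starts - target_time), starts)]
}

#' Select the per-day analysis segment under the discarded-IPI quality gate
#'
#' Walks the ordered candidate list and returns the first 300-s window whose
#' fraction of discarded inter-pulse intervals does not exceed the threshold
#' (20% in the study design). Quality is judged by the same IPI pipeline used
#' for the analysis itself, so the gate and the features share one number.
#'
#' @param candidates ordered start times from [candidate_windows()].
#' @param recording the [ppg_recording()] the candidates index into.
#' @param participant_id,day_index labels copied into the result.
#' @param duration window length, seconds.
#' @param max_discarded quality threshold on the discarded-IPI fraction.
#' @param ... passed to [ipi_series()] (e.g. detector settings).
#' @return a one-row data frame (class `segment_window`): participant_id,
#'   day_index, start, duration, discarded_ipi_fraction, accepted. When no
#'   candidate qualifies the best-quality candidate is returned with
#'   `accepted = FALSE`; with no candidates at all, `start` is `NA`.
#' @export
select_segment <- function(candidates, recording,
                           participant_id = NA_character_,
                           day_index = NA_integer_,
                           duration = 300, max_discarded = 0.20, ...) {
  stopifnot(inherits(recording, "ppg_recording"))
  res <- data.frame(participant_id = participant_id, day_index = day_index,
                    start = NA_real_, duration = duration,
                    discarded_ipi_fraction = NA_real_, accepted = FALSE,
                    stringsAsFactors = FALSE)
  class(res) <- c("segment_window", "data.frame")
  if (length(candidates) == 0L) return(res)
  best_frac <- Inf
  for (st in candidates) {
    seg <- slice_recording(recording, st, duration)
    frac <- tryCatch(ipi_series(seg, ...)$discarded_fraction,
                     error = function(e) 1)
    if (is.na(frac)) frac <- 1
    if (frac <= max_discarded) {
      res$start <- st
      res$discarded_ipi_fraction <- frac
      res$accepted <- TRUE
      return(res)
    }
    if (frac < best_frac) {
      best_frac <- frac
      res$start <- st
      res$discarded_ipi_fraction <- frac
    }
  }
  ppg_log(sprintf("%s day %s: no candidate met the %.0f%% gate (best %.1f%%)",
                  participant_id, day_index, 100 * max_discarded,
                  100 * best_frac))
  res
}

#' Extract a sub-recording by study-clock start time and duration
#'
#' @param recording a [ppg_recording()].
#' @param start,duration window position and length on the study clock, s.
#' @return a [ppg_recording()] covering the window.
#' @export
slice_recording <- function(recording, start, duration) {
  i1 <- as.integer(round((start - recording$start_time) * recording$fs)) + 1L
  n <- as.integer(round(duration * recording$fs))
  i2 <- min(i1 + n - 1L, length(recording$samples))
  if (i1 < 1L || i2 <= i1) stop("window outside recording span", call. = FALSE)
  out <- ppg_recording(recording$samples[i1:i2], recording$fs,
                       start_time = recording$start_time + (i1 - 1L) / recording$fs,
                       events = recording$events)
  bt <- attr(recording, "beat_times")
  if (!is.null(bt)) {
    attr(out, "beat_times") <-
      bt[bt >= out$start_time & bt <= out$start_time + duration]
  }
  out
}

#' Assign the drug-free baseline day for one participant
#'
#' The baseline is the pre-injection day-0 measurement when one was accepted;
#' otherwise the day-4 washout measurement (96 h after the first injection,
#' past several half-lives of the drug); otherwise the participant has no
#' baseline and is excluded from the paired analysis.
#'
#' @param available_days integer vector of day indices with accepted segments.
#' @return list with `baseline_day` (0, 4 or `NA`) and `source`
#'   (`"pre-injection"`, `"washout"` or `NA`).
#' @export
assign_baseline <- function(available_days) {
  if (0L %in% available_days) {
    list(baseline_day = 0L, source = "pre-injection")
  } else if (4L %in% available_days) {
    list(baseline_day = 4L, source = "washout")
  } else {
    list(baseline_day = NA_integer_, source = NA_character_)
  }
}

#' Run segment selection over a whole cohort
#'
#' For each manifest row, builds the day's target time (1 h before injection 1
#' for day 0, 24/48/72/96 h after injection 1 for days 1-4), enumerates
#' candidate windows (capping day 0 at injection 1 and day 1 at injection 2)
#' and applies the quality gate.
#'
#' @param cohort a `ppg_cohort`, or a list with `manifest` plus `recordings`
#'   keyed `"<participant>_d<day>"`.
#' @param tolerance_h tolerance around the daily target, hours.
#' @param max_discarded segment quality threshold.
#' @param ... passed to [select_segment()].
#' @return data frame of segment windows, one row per manifest entry.
#' @export
select_cohort_segments <- function(cohort, tolerance_h = 4,
                                   max_discarded = 0.20, ...) {
  man <- cohort$manifest
  out <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    row <- man[i, ]
    key <- sprintf("%s_d%d", row$participant_id, row$day)
    rec <- cohort$recordings[[key]]
    d <- row$day
    target <- if (d == 0L) row$injection1_time - 3600
              else row$injection1_time + d * 86400
    cap <- if (d == 0L) row$injection1_time
           else if (d == 1L) row$injection2_time
           else NULL
    cand <- candidate_windows(rec, target, tolerance = tolerance_h * 3600,
                              cap_time = cap)
    out[[i]] <- select_segment(cand, rec, participant_id = row$participant_id,
                               day_index = d, max_discarded = max_discarded,
                               ...)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
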