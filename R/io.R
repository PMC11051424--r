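#' Write a PPG recording as a two-column CSV
#'
#' Columns `time_s` (absolute study-clock seconds) and `ppg`. Event times are
#' not stored in the recording file; they travel in the cohort manifest.
#'
#' @param recording a [ppg_recording()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "ppg_recording"))
  utils::write.csv(
    data.frame(time_s = recording_times(recording),
               ppg = recording$samples),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a PPG recording from CSV
#'
#' Expects a header row with columns `time_s` and `ppg`. The sampling rate is
#' inferred from the median time step and validated against the whole time
#' column: any deviation beyond half a sample period is either flagged as a
#' gap (when the time column jumps forward) or rejected (when it is
#' non-monotonic).
#'
#' @param path CSV file path.
#' @param events optional named numeric vector of event times to attach.
#' @return a [ppg_recording()]; gaps larger than two sample periods are
#'   reported via attribute `"gaps"` (data frame of row index and gap length)
#'   and a log message.
#' @export
read_recording <- function(path, events = numeric(0)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty recording file: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (!all(c("time_s", "ppg") %in% names(df))) {
    stop("recording CSV must have header columns `time_s` and `ppg`: ", path,
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("empty recording file: ", path, call. = FALSE)
  dt <- diff(df$time_s)
  bad <- which(dt <= 0)
  if (length(bad)) {
    stop(sprintf("non-monotonic time column in %s at row %d", path, bad[1] + 1L),
         call. = FALSE)
  }
  fs <- 1 / stats::median(dt)
  gap_rows <- which(dt > 2 / fs)
  gaps <- data.frame(row = gap_rows, gap_s = dt[gap_rows])
  if (nrow(gaps)) {
    ppg_log(sprintf("%s: %d gap(s) > 2 samples, longest %.2f s",
                    basename(path), nrow(gaps), max(gaps$gap_s)))
  }
  small_dev <- abs(dt - 1 / fs) < 0.5 / fs
  if (!all(small_dev | dt > 2 / fs)) {
    ppg_log(sprintf("%s: irregular sampling beyond half a period at %d rows",
                    basename(path), sum(!small_dev & dt <= 2 / fs)))
  }
  rec <- ppg_recording(df$ppg, fs, start_time = df$time_s[1], events = events)
  attr(rec, "gaps") <- gaps
  rec
}

#' Read a cohort manifest CSV
#'
#' @param path path to a `manifest.csv` written by [write_cohort()] (columns
#'   participant_id, day, file, start_time, injection1_time, injection2_time).
#' @return a data frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "day", "file", "start_time",
            "injection1_time", "injection2_time")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}
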