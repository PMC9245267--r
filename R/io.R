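# CSV dialects: headered, comma-delimited, '.' decimal; times as ms floats.

#' Read and write signal CSV files
#'
#' The signal dialect has two required columns, `time_ms` and `amplitude`,
#' uniformly sampled. The sampling rate is inferred from the median time
#' step on read.
#'
#' @param path File path.
#' @return `read_ecg_csv`: an [ecg_signal()].
#' @export
read_ecg_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("time_ms", "amplitude") %in% names(df)))
    stopf("'%s': expected columns time_ms, amplitude", path)
  if (nrow(df) < 2L) stopf("'%s': need >= 2 samples", path)
  bad <- which(!is.finite(df$time_ms) | !is.finite(df$amplitude))
  if (length(bad))
    stopf("'%s': non-numeric value at data row %d", path, bad[1])
  step <- median(diff(df$time_ms))
  ecg_signal(df$amplitude, fs = 1000 / step, t0_ms = df$time_ms[1])
}

#' @rdname read_ecg_csv
#' @param signal An [ecg_signal()].
#' @export
write_ecg_csv <- function(signal, path) {
  stopifnot(inherits(signal, "ecg_signal"))
  write.csv(data.frame(time_ms = signal_times(signal),
                       amplitude = signal$samples),
            path, row.names = FALSE)
  invisible(path)
}

#' Read and write timing-table CSV files
#'
#' Event timing tables have columns `event` (e.g. `"ac"`, `"marker"`),
#' `time_ms`, and `clock` (`"ecg"` or `"dus"`).
#'
#' @param path File path.
#' @return `read_timing_csv`: a data frame with the three columns.
#' @export
read_timing_csv <- function(path) {
  df <- read.csv(path)
  need <- c("event", "time_ms", "clock")
  if (!all(need %in% names(df)))
    stopf("'%s': expected columns %s", path, paste(need, collapse = ", "))
  if (!all(df$clock %in% c("ecg", "dus")))
    stopf("'%s': clock must be 'ecg' or 'dus'", path)
  df[need]
}

#' @rdname read_timing_csv
#' @param timing Data frame with columns `event`, `time_ms`, `clock`.
#' @export
write_timing_csv <- function(timing, path) {
  write.csv(timing[c("event", "time_ms", "clock")], path, row.names = FALSE)
  invisible(path)
}

# assemble the timing table for one simulated recording
timing_table <- function(dus) {
  rbind(
    data.frame(event = "marker", time_ms = dus$markers_ecg_ms, clock = "ecg"),
    data.frame(event = "marker", time_ms = dus$markers_dus_ms, clock = "dus"),
    data.frame(event = "ac", time_ms = dus$ac_times_ms, clock = "dus")
  )
}

#' Read and write beat-table CSV files
#'
#' Columns: `beat_index`, `q_time_ms`, `r_time_ms`, `rr_ms`, `k`,
#' `t_end_ms`, `qt_ms` (as produced by [build_beat_table()]).
#'
#' @param path File path.
#' @return `read_beat_table_csv`: a `beat_table` data frame.
#' @export
read_beat_table_csv <- function(path) {
  df <- read.csv(path)
  need <- c("beat_index", "q_time_ms", "r_time_ms", "rr_ms", "k",
            "t_end_ms", "qt_ms")
  if (!all(need %in% names(df)))
    stopf("'%s': expected columns %s", path, paste(need, collapse = ", "))
  df <- df[need]
  class(df) <- c("beat_table", "data.frame")
  df
}

#' @rdname read_beat_table_csv
#' @param beats A `beat_table` data frame.
#' @export
write_beat_table_csv <- function(beats, path) {
  write.csv(as.data.frame(beats), path, row.names = FALSE)
  invisible(path)
}
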