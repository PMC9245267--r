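# Workflow entry points: simulate -> estimate -> validate. Each writes
# machine-readable files and returns its results invisibly; the exec/qtdecay
# script is a thin shell over these.

#' Simulate a recording to disk
#'
#' Writes `signal.csv` (signal dialect), `truth.csv` (ground-truth beat
#' fiducials), `timing.csv` (Ac events and marker pulses on both clocks)
#' and `manifest.json` (the full configuration and seed, for exact
#' regeneration) into `out_dir`.
#'
#' @param config A [sim_config()]; give it a `seed` for reproducible files.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a named list of the written paths.
#' @export
run_simulate <- function(config = sim_config(), out_dir) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  rec <- simulate_recording(config)
  paths <- list(signal = file.path(out_dir, "signal.csv"),
                truth = file.path(out_dir, "truth.csv"),
                timing = file.path(out_dir, "timing.csv"),
                manifest = file.path(out_dir, "manifest.json"))
  write_ecg_csv(rec$signal, paths$signal)
  write.csv(rec$truth, paths$truth, row.names = FALSE)
  write_timing_csv(timing_table(rec$dus), paths$timing)
  manifest <- config[!vapply(config, is.null, logical(1))]
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Estimate beat-by-beat QT intervals from a signal file
#'
#' Reads a signal CSV, runs fiducial detection and the decay-model QT
#' estimator, and writes `beat_table.csv` plus `summary.json`
#' (mean +/- SD of RR and QT, beat count).
#'
#' @param signal_path Signal CSV (columns `time_ms`, `amplitude`).
#' @param out_dir Output directory (created if missing).
#' @param config A [model_config()].
#' @param ... Passed to [build_beat_table()] (detection parameters).
#' @return Invisibly, list with `beats` (the beat table), `summary` and the
#'   written `paths`.
#' @export
run_estimate <- function(signal_path, out_dir, config = model_config(), ...) {
  signal <- read_ecg_csv(signal_path)
  beats <- build_beat_table(signal, config, ...)
  summ <- summarize_record(beats)
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  paths <- list(beats = file.path(out_dir, "beat_table.csv"),
                summary = file.path(out_dir, "summary.json"))
  write_beat_table_csv(beats, paths$beats)
  jsonlite::write_json(c(as.list(summ),
                         list(species = config$species, fs = config$fs)),
                       paths$summary, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(beats = beats, summary = summ, paths = paths))
}

#' Validate model QT intervals against Doppler Q-Ac intervals
#'
#' Reads a beat table and a timing table, aligns the Doppler clock onto the
#' ECG clock via the shared markers, computes per-beat Q-Ac intervals, and
#' writes a JSON agreement report: clock offset and residual SD, pair
#' count, Bland-Altman bias and limits, percentage of differences within
#' the limits, Pearson r, and the mean absolute difference percentage
#' (Q-Ac as reference).
#'
#' @param beats_path Beat-table CSV from [run_estimate()].
#' @param timing_path Timing CSV with `marker` rows on both clocks and `ac`
#'   rows on the DUS clock.
#' @param out_path Output JSON path.
#' @return Invisibly, the report as a list.
#' @export
run_validate <- function(beats_path, timing_path, out_path) {
  beats <- read_beat_table_csv(beats_path)
  timing <- read_timing_csv(timing_path)
  mk_ecg <- timing$time_ms[timing$event == "marker" & timing$clock == "ecg"]
  mk_dus <- timing$time_ms[timing$event == "marker" & timing$clock == "dus"]
  ac <- timing$time_ms[timing$event == "ac" & timing$clock == "dus"]
  if (length(ac) == 0L) stopf("'%s': no 'ac' events on the dus clock", timing_path)
  aln <- align_by_markers(mk_ecg, mk_dus)
  qac <- q_ac_intervals(beats$q_time_ms, ac, aln$offset_ms)
  qt <- beats$qt_ms[qac$beat]
  agree <- bland_altman(qt, qac$q_ac_ms)
  report <- list(
    n = agree$n,
    n_dropped_ac = attr(qac, "n_dropped"),
    clock_offset_ms = aln$offset_ms,
    marker_residual_sd_ms = aln$residual_sd_ms,
    bias_ms = agree$bias,
    loa_low_ms = agree$loa_low,
    loa_high_ms = agree$loa_high,
    pct_within_loa = agree$pct_within,
    pearson_r = agree$r,
    mean_abs_diff_pct = mean_abs_difference_pct(qac$q_ac_ms, qt)
  )
  dir_out <- dirname(out_path)
  if (!dir.exists(dir_out)) dir.create(dir_out, recursive = TRUE)
  jsonlite::write_json(report, out_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(report)
}
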