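#' Clock alignment from shared marker pulses
#'
#' The ECG and Doppler systems run on independent clocks; a pulse generator
#' feeds the same marker pulses to both during recording. Matching the
#' marker timestamps gives the constant clock offset: subtracting the
#' offset from a Doppler timestamp maps it onto the ECG clock.
#'
#' @param ecg_markers,dus_markers Marker pulse times (ms) on each system's
#'   clock; same count, sorted ascending, matched one-to-one in order.
#' @return An object of class `marker_alignment`: list with `offset_ms`
#'   (mean of per-marker `dus - ecg` differences), `residual_sd_ms`,
#'   `residuals_ms` and `n`. A residual SD above 5 ms triggers a warning
#'   (likely marker mismatch).
#' @examples
#' align_by_markers(c(10, 50, 90), c(1010, 1050, 1090))  # offset 1000
#' @export
align_by_markers <- function(ecg_markers, dus_markers) {
  if (length(ecg_markers) < 1L || length(dus_markers) < 1L)
    stopf("need at least one marker on each clock")
  if (length(ecg_markers) != length(dus_markers))
    stopf("marker counts differ (%d ECG vs %d DUS); cannot pair markers",
          length(ecg_markers), length(dus_markers))
  if (is.unsorted(ecg_markers) || is.unsorted(dus_markers))
    stopf("marker times must be sorted ascending on each clock")
  d <- dus_markers - ecg_markers
  offset <- mean(d)
  res <- d - offset
  rsd <- if (length(d) > 1L) sd(d) else 0
  if (rsd > 5)
    warning(sprintf("marker residual SD %.2f ms > 5 ms: possible marker mismatch",
                    rsd), call. = FALSE)
  structure(list(offset_ms = offset, residual_sd_ms = rsd,
                 residuals_ms = res, n = length(d)),
            class = "marker_alignment")
}

#' @export
print.marker_alignment <- function(x, ...) {
  cat(sprintf("<marker_alignment> offset = %.3f ms (n = %d, residual SD %.3f ms)\n",
              x$offset_ms, x$n, x$residual_sd_ms))
  invisible(x)
}

#' Q-to-aortic-closure intervals
#'
#' Maps Doppler aortic-closure (Ac) timestamps onto the ECG clock and
#' assigns each to the beat whose Q fiducial most recently precedes it
#' (one-to-one). The Q-Ac interval — the mechanical surrogate for the QT
#' interval — is `(ac - offset) - q`.
#'
#' Ac events falling before the first Q or beyond the matched beat's span
#' are dropped; beats without an Ac are likewise dropped. Two Ac events in
#' one beat is an error.
#'
#' @param q_times Q fiducial times (ms, ECG clock), sorted ascending.
#' @param ac_times Ac event times (ms, DUS clock).
#' @param offset_ms Clock offset from [align_by_markers()] (`dus - ecg`).
#' @param max_interval_ms Upper bound on a valid Q-Ac interval for the last
#'   beat (interior beats are bounded by the next Q). Default: the median
#'   Q-to-Q spacing.
#' @return Data frame with `beat`, `q_time_ms`, `ac_time_ms` (ECG clock)
#'   and `q_ac_ms`; attribute `n_dropped` counts unmatched Ac events.
#' @examples
#' q_ac_intervals(100, 1240, offset_ms = 1000)  # 140 ms
#' @export
q_ac_intervals <- function(q_times, ac_times, offset_ms,
                           max_interval_ms = NULL) {
  if (is.unsorted(q_times)) stopf("'q_times' must be sorted ascending")
  ac <- sort(ac_times) - offset_ms
  if (is.null(max_interval_ms))
    max_interval_ms <- if (length(q_times) > 1L) median(diff(q_times)) else Inf
  idx <- findInterval(ac, q_times)
  upper <- c(q_times[-1L], q_times[length(q_times)] + max_interval_ms)
  ok <- idx >= 1L & ac > q_times[pmax(idx, 1L)] & ac < upper[pmax(idx, 1L)]
  matched <- idx[ok]
  if (anyDuplicated(matched))
    stopf("ambiguous matching: multiple Ac events in beat(s) %s",
          paste(unique(matched[duplicated(matched)]), collapse = ", "))
  out <- data.frame(beat = matched,
                    q_time_ms = q_times[matched],
                    ac_time_ms = ac[ok],
                    q_ac_ms = ac[ok] - q_times[matched])
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Difference percentage between a reference and an estimate
#'
#' Signed per-beat relative difference,
#' \deqn{100 \cdot (\mathrm{ref} - \mathrm{est}) / \mathrm{ref},}
#' used to compare two measurers' Q-Ac readings and to compare model QT
#' intervals against Q-Ac. Record-level summaries report the mean of the
#' per-beat absolute values (see [mean_abs_difference_pct()]).
#'
#' @param reference Reference interval(s), ms; must be positive.
#' @param estimate Estimate interval(s), ms. Recycled against `reference`.
#' @return Signed percentage(s).
#' @examples
#' difference_percentage(134, 133)  # 0.746
#' @export
difference_percentage <- function(reference, estimate) {
  if (any(!is.finite(reference)) || any(reference <= 0))
    stopf("'reference' must be positive and finite")
  100 * (reference - estimate) / reference
}

#' @rdname difference_percentage
#' @export
mean_abs_difference_pct <- function(reference, estimate) {
  mean(abs(difference_percentage(reference, estimate)))
}

#' Bland-Altman agreement statistics
#'
#' Computes the standard Bland-Altman agreement summary for paired
#' measurements: differences `d = a - b`, bias = mean(d), limits of
#' agreement = bias +/- 1.96 * SD(d) (sample SD, n - 1), the percentage of
#' pairs inside the limits (inclusive), and the Pearson correlation of `a`
#' against `b`. Under normally distributed differences about 95% of pairs
#' fall within the limits.
#'
#' @param a,b Paired measurements, equal length >= 3.
#' @return An object of class `agreement_stats`: list with `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `pct_within`, `r` (`NA` if either
#'   series has zero variance) and `n`.
#' @examples
#' bland_altman(c(140, 150, 145), c(138, 152, 145))
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stopf("'a' and 'b' must have equal length")
  if (length(a) < 3L) stopf("need >= 3 pairs for agreement limits")
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  loa_low <- bias - 1.96 * s
  loa_high <- bias + 1.96 * s
  r <- if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b)
  structure(
    list(bias = bias, sd_diff = s, loa_low = loa_low, loa_high = loa_high,
         pct_within = 100 * mean(d >= loa_low & d <= loa_high),
         r = r, n = length(d)),
    class = "agreement_stats"
  )
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat("<agreement_stats>\n")
  cat(sprintf("  n = %d   bias = %.3f ms   LoA [%.3f, %.3f] ms\n",
              x$n, x$bias, x$loa_low, x$loa_high))
  cat(sprintf("  %.1f%% of pairs within limits   Pearson r = %s\n",
              x$pct_within,
              if (is.na(x$r)) "NA (zero variance)" else sprintf("%.4f", x$r)))
  invisible(x)
}
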