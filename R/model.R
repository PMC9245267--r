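#' Model configuration
#'
#' Bundles the parameters of the repolarization-decay QT model. The model
#' treats the ventricular repolarization phase like the discharge of a
#' capacitor: the per-beat decay curve \eqn{R(t) = v_0 e^{-2\pi t / RR}}
#' falls from \code{v0} at the R peak towards zero over one RR interval,
#' and the end of the T wave is read off where the curve crosses a
#' rate-dependent threshold band (see [threshold_k()] and [t_end()]).
#'
#' @param v0 Initial amplitude of the decay curve (dimensionless). The
#'   canonical value is 100, which puts the threshold constant `k` on a
#'   convenient scale.
#' @param fs Sampling rate in Hz at which the decay curve is discretized.
#'   1000 Hz matches typical fetal ECG acquisition and gives millisecond
#'   resolution.
#' @param species `"mouse"` or `"human"`. Mouse action potentials are much
#'   shorter than human ones (repolarization is dominated by the transient
#'   outward potassium current), so the mouse threshold *adds* a
#'   \eqn{2\pi/x^2} term where the human variant *subtracts* \eqn{6\pi/x^2},
#'   pulling the estimated T end earlier in the beat.
#' @param qr_offset_ms Q-to-R interval in ms used when a QT interval is
#'   assembled from an RR interval alone (no ECG waveform available). The
#'   decay curve is anchored at the R peak, so QT = (R - Q) + T_E; 8 ms is a
#'   typical fetal mouse Q-R separation. When beats are extracted from a
#'   signal the measured per-beat R - Q replaces this default.
#'
#' @return An object of class `model_config`.
#' @examples
#' model_config()
#' model_config(species = "human")
#' @export
model_config <- function(v0 = 100, fs = 1000,
                         species = c("mouse", "human"),
                         qr_offset_ms = 8) {
  species <- match.arg(species)
  check_number(v0, "v0", lower = 0, strict = TRUE)
  check_number(fs, "fs", lower = 0, strict = TRUE)
  check_number(qr_offset_ms, "qr_offset_ms", lower = 0)
  structure(
    list(v0 = v0, fs = fs, species = species, qr_offset_ms = qr_offset_ms),
    class = "model_config"
  )
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>\n")
  cat(sprintf("  species: %s   v0: %g   fs: %g Hz   Q-R offset: %g ms\n",
              x$species, x$v0, x$fs, x$qr_offset_ms))
  invisible(x)
}

#' Repolarization decay amplitude
#'
#' Evaluates the per-beat decay curve \eqn{R(t) = v_0 e^{-2\pi t / RR}} at
#' time `t_ms` after the R peak. The \eqn{2\pi} rate constant arises from
#' identifying the RC time constant of a discharging capacitor with
#' \eqn{RR / 2\pi} (the cut-off frequency is taken as the heart rate).
#'
#' @param t_ms Time(s) since the R peak, in ms. Vectorized.
#' @param rr_ms RR interval of the beat, in ms (single positive number).
#' @param v0 Initial amplitude; defaults to 100.
#' @return Amplitude(s), same length as `t_ms`; strictly decreasing in `t_ms`.
#' @examples
#' decay_amplitude(0, 256)            # 100
#' decay_amplitude(128, 256)          # 100 * exp(-pi)
#' @export
decay_amplitude <- function(t_ms, rr_ms, v0 = 100) {
  check_number(rr_ms, "rr_ms", lower = 0, strict = TRUE)
  check_number(v0, "v0", lower = 0, strict = TRUE)
  if (any(!is.finite(t_ms)) || any(t_ms < 0))
    stopf("'t_ms' must be finite and >= 0")
  v0 * exp(-2 * pi * t_ms / rr_ms)
}

#' Sample the decay curve for one beat
#'
#' Discretizes the decay curve on the sampling grid `t = 0, 1/fs, ...` up to
#' (but excluding) `rr_ms`.
#'
#' @param rr_ms RR interval in ms. Must allow at least two samples.
#' @param config A [model_config()].
#' @return An object of class `decay_curve`: a list with `rr_ms`, `times_ms`,
#'   `amplitudes`, `v0` and `fs`.
#' @examples
#' curve <- sample_decay(256)
#' length(curve$times_ms)  # 256 at fs = 1000
#' @export
sample_decay <- function(rr_ms, config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  check_number(rr_ms, "rr_ms", lower = 0, strict = TRUE)
  step <- 1000 / config$fs
  if (rr_ms < 2 * step)
    stopf("rr_ms = %g ms is too short for >= 2 samples at fs = %g Hz",
          rr_ms, config$fs)
  times <- seq(0, rr_ms - step / 2, by = step)
  structure(
    list(rr_ms = rr_ms,
         times_ms = times,
         amplitudes = decay_amplitude(times, rr_ms, config$v0),
         v0 = config$v0, fs = config$fs),
    class = "decay_curve"
  )
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("<decay_curve> RR = %g ms, %d samples at %g Hz, v0 = %g\n",
              x$rr_ms, length(x$times_ms), x$fs, x$v0))
  invisible(x)
}

#' Threshold constant k and its band
#'
#' Computes the rate-dependent threshold constant
#' \deqn{k = \left| \mathrm{mean}(R(t))/x \pm c\pi/x^2 \right|}
#' where \eqn{x = 1000/RR} is the instantaneous heart rate in Hz, the sign
#' and coefficient of the correction term are species dependent (mouse:
#' \eqn{+2\pi/x^2}; human: \eqn{-6\pi/x^2}), and mean(R(t)) is the mean of
#' the decay curve over one beat. The T-wave end is then located inside the
#' amplitude band (k - 0.5, k + 1).
#'
#' The per-beat mean is computed by trapezoidal integration of the sampled
#' curve over the full period \eqn{[0, RR]}; this converges to the
#' closed-form period mean \eqn{v_0 (1 - e^{-2\pi}) / 2\pi \approx 15.886}
#' (for \eqn{v_0 = 100}) and is accurate to O(1/fs^2).
#'
#' @inheritParams sample_decay
#' @return An object of class `threshold_params`: list with `rr_ms`, `x`
#'   (1/RR in s^-1), `mean_amp`, `k`, `band_low` (= k - 0.5), `band_high`
#'   (= k + 1) and `species`.
#' @examples
#' threshold_k(256)  # mouse: k ~ 4.48
#' @export
threshold_k <- function(rr_ms, config = model_config()) {
  curve <- sample_decay(rr_ms, config)
  x <- 1000 / rr_ms
  # close the period with the endpoint amplitude so the trapezoid spans [0, RR]
  tt <- c(curve$times_ms, rr_ms)
  aa <- c(curve$amplitudes, decay_amplitude(rr_ms, rr_ms, config$v0))
  mean_amp <- pracma::trapz(tt, aa) / rr_ms
  term <- switch(config$species,
                 mouse = 2 * pi / x^2,
                 human = -6 * pi / x^2)
  k <- abs(mean_amp / x + term)
  structure(
    list(rr_ms = rr_ms, x = x, mean_amp = mean_amp, k = k,
         band_low = k - 0.5, band_high = k + 1, species = config$species),
    class = "threshold_params"
  )
}

#' @export
print.threshold_params <- function(x, ...) {
  cat(sprintf(
    "<threshold_params> RR = %g ms (x = %.4f /s, %s): k = %.4f, band (%.4f, %.4f)\n",
    x$rr_ms, x$x, x$species, x$k, x$band_low, x$band_high))
  invisible(x)
}

#' T-wave end from the threshold band
#'
#' The estimated end of the T wave is the median of the sample times whose
#' decay amplitude lies strictly inside the band \eqn{(k - 0.5, k + 1)}:
#' \deqn{T_E = \mathrm{median}\{ t : k - 0.5 < R(t) < k + 1 \}.}
#' For an even number of in-band samples the median is the mean of the two
#' central times. Times are relative to the R peak.
#'
#' @param curve A [sample_decay()] result.
#' @param params A [threshold_k()] result (the band may be overridden by
#'   supplying a modified object).
#' @return T-end time in ms, strictly inside (0, RR).
#' @examples
#' cfg <- model_config()
#' t_end(sample_decay(256, cfg), threshold_k(256, cfg))  # ~125 ms
#' @export
t_end <- function(curve, params) {
  stopifnot(inherits(curve, "decay_curve"))
  a <- curve$amplitudes
  sel <- a > params$band_low & a < params$band_high
  if (!any(sel))
    stopf(paste0("no samples fall inside the threshold band (%.3f, %.3f); ",
                 "the sampling rate may be too low or RR = %g ms outside the ",
                 "model's range"),
          params$band_low, params$band_high, curve$rr_ms)
  median(curve$times_ms[sel])
}

#' QT interval from an RR interval
#'
#' Assembles the model QT interval for one or more RR intervals:
#' `qt_ms = qr_offset_ms + t_end`, with the T end predicted from RR alone.
#' This is the estimator used when no measurable T wave exists on the ECG —
#' the premise for fetal mice, whose T waves are too small to measure.
#'
#' @param rr_ms RR interval(s) in ms.
#' @inheritParams sample_decay
#' @return A data frame of class `qt_estimate` with one row per RR:
#'   columns `rr_ms`, `k`, `t_end_ms`, `qt_ms`.
#' @examples
#' qt_from_rr(c(256, 390))  # ~133, ~170 ms
#' @export
qt_from_rr <- function(rr_ms, config = model_config()) {
  rows <- lapply(rr_ms, function(rr) {
    params <- threshold_k(rr, config)
    te <- t_end(sample_decay(rr, config), params)
    data.frame(rr_ms = rr, k = params$k, t_end_ms = te,
               qt_ms = config$qr_offset_ms + te)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("qt_estimate", "data.frame")
  out
}
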