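#' Flow-rate waveform
#'
#' A `T`-periodic flow-rate waveform `Q(t)` sampled at phase times
#' `t_k` in `[0, T)`. The cycle mean is reported but not forced to zero.
#'
#' @param t phase times in seconds, strictly increasing, all in `[0, period)`.
#' @param Q flow rate in mL/s at the phase times (unit out-of-plane depth for
#'   two-dimensional flows).
#' @param period oscillation period `T` in seconds.
#' @return an object of class `flow_waveform`.
#' @export
flow_waveform <- function(t, Q, period) {
  if (length(t) == 0L) stop("empty waveform")
  if (length(t) != length(Q)) stop("t and Q must have equal length")
  if (any(diff(t) <= 0)) stop("waveform phase times must be strictly increasing")
  if (!(period > 0)) stop("period must be positive")
  if (any(t < 0) || any(t >= period)) stop("phase times must lie in [0, period)")
  structure(list(t = as.numeric(t), Q = as.numeric(Q), period = period),
            class = "flow_waveform")
}

#' Single-harmonic sine waveform
#'
#' Convenience constructor for `Q(t) = Q0 sin(2 pi t / T) + Q_mean`, sampled
#' densely enough that trapezoidal cycle integrals are accurate.
#'
#' @param Q0 amplitude in mL/s.
#' @param period period `T` in s.
#' @param n number of samples per cycle.
#' @param Q_mean cycle-mean flow rate (mL/s), zero by default.
#' @return a [flow_waveform()].
#' @export
harmonic_waveform <- function(Q0, period = 1, n = 2000L, Q_mean = 0) {
  t <- (seq_len(n) - 1) * period / n
  flow_waveform(t, Q0 * sin(2 * pi * t / period) + Q_mean, period)
}

#' Evaluate a waveform at arbitrary times (periodic linear interpolation)
#'
#' @param wf a [flow_waveform()].
#' @param t times in seconds (any real values; the waveform is T-periodic).
#' @return flow rate in mL/s.
#' @export
waveform_at <- function(wf, t) {
  tp <- wf$t
  qp <- wf$Q
  tm <- t %% wf$period
  # append the wrapped first sample to close the cycle
  stats::approx(c(tp, tp[1] + wf$period), c(qp, qp[1]), xout = tm,
                method = "linear", rule = 2)$y
}

#' @method print flow_waveform
#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf("<flow_waveform> %d samples, T = %.4g s, max|Q| = %.4g mL/s, <Q> = %.4g mL/s\n",
              length(x$t), x$period, max(abs(x$Q)), waveform_mean(x)))
  invisible(x)
}

# cycle mean by periodic trapezoid
waveform_mean <- function(wf) {
  periodic_trapz(wf$t, wf$Q, wf$period) / wf$period
}

# trapezoidal integral over one full period with periodic closure
periodic_trapz <- function(t, y, period) {
  tt <- c(t, t[1] + period)
  yy <- c(y, y[1])
  sum(0.5 * (yy[-1] + yy[-length(yy)]) * diff(tt))
}

#' Stroke volume and dimensionless stroke length
#'
#' The stroke volume is half the cycle integral of the absolute flow rate,
#' `V_s = 0.5 * integral over one period of |Q| dt` (trapezoidal quadrature
#' with periodic closure), and the dimensionless stroke length is
#' `epsilon = V_s / reference_volume`, the ratio of the stroke volume to the
#' fluid volume of one canal segment. `epsilon << 1` is the regime where the
#' asymptotic streaming-plus-Stokes-drift formula for the mean Lagrangian
#' velocity is strictly valid.
#'
#' @param waveform a [flow_waveform()].
#' @param reference_volume segment fluid volume in mL; must be positive.
#' @return a list with components `V_s` (mL) and `epsilon` (dimensionless).
#' @export
stroke_volume_and_epsilon <- function(waveform, reference_volume) {
  if (!inherits(waveform, "flow_waveform")) stop("waveform must be a flow_waveform")
  if (!(reference_volume > 0)) stop("reference_volume must be positive")
  V_s <- 0.5 * periodic_trapz(waveform$t, abs(waveform$Q), waveform$period)
  list(V_s = V_s, epsilon = V_s / reference_volume)
}

#' Scale a waveform by a constant factor
#'
#' @param wf a [flow_waveform()].
#' @param factor multiplicative factor applied to `Q`.
#' @return a [flow_waveform()].
#' @export
scale_waveform <- function(wf, factor) {
  flow_waveform(wf$t, wf$Q * factor, wf$period)
}

#' Two-point linear interpolation
#'
#' Utility used, e.g., to interpolate tabulated effective-diffusivity
#' measurements to an intermediate stroke volume.
#'
#' @param x abscissa at which to interpolate.
#' @param x0,y0,x1,y1 the two known points.
#' @return interpolated ordinate.
#' @export
linear_interpolate <- function(x, x0, y0, x1, y1) {
  y0 + (y1 - y0) * (x - x0) / (x1 - x0)
}
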