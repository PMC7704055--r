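#' Lognormal bump-like waveform
#'
#' The canonical smooth description of a quantum bump or impulse response:
#' \deqn{v(t) = A \exp\left(-\frac{[\ln(t/t_p)]^2}{2 w^2}\right), \quad t > 0}
#' and 0 for \eqn{t \le 0}. `A` is the peak amplitude (pA or mV; negative
#' for inward current), `t_p` the peak time in ms, and `w` the
#' dimensionless log-domain shape width.
#'
#' The half-width (width at 50% of peak) has the closed form
#' \eqn{h = 2 t_p \sinh(w \sqrt{2 \ln 2})}: the two half-maximum crossings
#' sit at \eqn{t_p e^{\pm w\sqrt{2\ln 2}}}.
#'
#' @param amplitude peak value `A`; any non-zero number.
#' @param t_peak peak time `t_p` in ms; must be positive.
#' @param shape log-domain width `w`; must be positive.
#' @return an object of class `lognormal_waveform`.
#' @seealso [gen_lognormal_qb()] to construct from a target half-width,
#'   [waveform_halfwidth()] for the closed form, [eval_waveform()].
#' @export
lognormal_waveform <- function(amplitude, t_peak, shape) {
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L, amplitude != 0,
            is.numeric(t_peak), length(t_peak) == 1L, t_peak > 0,
            is.numeric(shape), length(shape) == 1L, shape > 0)
  structure(list(amplitude = amplitude, t_peak = t_peak, shape = shape),
            class = "lognormal_waveform")
}

#' Evaluate a lognormal waveform on a time grid
#'
#' @param wf a [lognormal_waveform()].
#' @param t numeric vector of times in ms; values at `t <= 0` are 0.
#' @return numeric vector of waveform values.
#' @export
eval_waveform <- function(wf, t) {
  stopifnot(inherits(wf, "lognormal_waveform"))
  v <- numeric(length(t))
  pos <- t > 0
  v[pos] <- wf$amplitude * exp(-(log(t[pos] / wf$t_peak))^2 / (2 * wf$shape^2))
  v
}

#' Closed-form half-width of a lognormal waveform
#'
#' @param wf a [lognormal_waveform()].
#' @return width at 50% of peak, ms.
#' @export
waveform_halfwidth <- function(wf) {
  stopifnot(inherits(wf, "lognormal_waveform"))
  2 * wf$t_peak * sinh(wf$shape * sqrt(2 * log(2)))
}

#' @export
print.lognormal_waveform <- function(x, ...) {
  cat(sprintf(
    "<lognormal_waveform> A = %.4g, t_peak = %.4g ms, shape = %.4g (half-width %.4g ms)\n",
    x$amplitude, x$t_peak, x$shape, waveform_halfwidth(x)))
  invisible(x)
}

#' Generate a QB-like lognormal waveform with a prescribed half-width
#'
#' Solves the shape width in closed form so that the waveform's measured
#' half-width equals the request: \eqn{w = \mathrm{asinh}(h / 2 t_p) /
#' \sqrt{2 \ln 2}}. By convention the peak time defaults to 1.5 times the
#' half-width, which gives a realistically skewed bump (slow decay
#' relative to rise).
#'
#' @param half_width target width at 50% of peak, ms (> 0).
#' @param amplitude peak amplitude; defaults to -1 (unit inward current).
#' @param t_peak peak time, ms; default `1.5 * half_width`.
#' @return a [lognormal_waveform()] whose [waveform_halfwidth()] equals
#'   `half_width` exactly.
#' @examples
#' wf <- gen_lognormal_qb(4)
#' waveform_halfwidth(wf)  # 4
#' @export
gen_lognormal_qb <- function(half_width, amplitude = -1, t_peak = 1.5 * half_width) {
  stopifnot(is.numeric(half_width), length(half_width) == 1L,
            is.finite(half_width), half_width > 0)
  if (!is.finite(t_peak) || t_peak <= 0)
    stop("no lognormal waveform exists for t_peak <= 0 at half_width = ",
         half_width)
  w <- asinh(half_width / (2 * t_peak)) / sqrt(2 * log(2))
  lognormal_waveform(amplitude = amplitude, t_peak = t_peak, shape = w)
}

# Default sampling grid for a waveform: from 0 until it has decayed below
# `tail_frac` of peak, at step dt.
waveform_grid <- function(wf, dt = 0.1, tail_frac = 0.001) {
  # decay crossing: |v| = tail_frac * |A| at t = t_p * exp(w * sqrt(-2 log(tail_frac)))
  t_end <- wf$t_peak * exp(wf$shape * sqrt(-2 * log(tail_frac)))
  seq(0, t_end + dt, by = dt)
}

#' Sample a waveform into a trace data frame
#'
#' @param wf a [lognormal_waveform()].
#' @param dt sampling step, ms.
#' @param t optional explicit time grid (overrides `dt`).
#' @return data.frame with columns `time_ms`, `value`.
#' @export
sample_waveform <- function(wf, dt = 0.1, t = NULL) {
  if (is.null(t)) t <- waveform_grid(wf, dt)
  data.frame(time_ms = t, value = eval_waveform(wf, t))
}
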