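#' Flicker frequency response of a waveform
#'
#' Imitates the response to a train of instantaneous flashes: for each
#' frequency `f` the waveform is replicated at period `1000/f` ms and
#' summed until steady state (adding one more copy changes the windowed
#' max and min by < 0.01%), then the signal is read over a central window
#' of at least three periods as `(max - min) / max` of the summed
#' magnitude trace. A frequency much slower than the waveform duration
#' gives signal 1 (isolated pulses); fast flicker fuses into a nearly
#' flat trace and the signal falls towards 0.
#'
#' @param waveform a [lognormal_waveform()] or a sampled trace
#'   (data.frame / numeric + `time`). The waveform must decay below 1% of
#'   its peak within its sampled domain.
#' @param frequencies stimulation frequencies in Hz (default the standard
#'   set 5, 12.5, 25, 50, 100, 200 Hz, i.e. shifts of 200, 80, 40, 20,
#'   10, 5 ms).
#' @param dt evaluation grid, ms.
#' @return an object of class `freq_response`: data.frame with columns
#'   `frequency_hz` and `signal`.
#' @export
flicker_response <- function(waveform,
                             frequencies = c(5, 12.5, 25, 50, 100, 200),
                             dt = 0.1) {
  stopifnot(all(frequencies > 0))
  if (inherits(waveform, "lognormal_waveform")) {
    t <- waveform_grid(waveform, dt = dt, tail_frac = 1e-4)
    y <- abs(eval_waveform(waveform, t))
  } else {
    tr <- as_trace_xy(waveform)
    dt <- diff(tr$t[1:2])
    y <- abs(tr$y)
    t <- tr$t
  }
  pk <- max(y)
  if (y[length(y)] > 0.01 * pk)
    stop("waveform does not decay below 1% of peak within its domain")
  sig <- vapply(frequencies, function(f) {
    period <- 1000 / f
    np <- max(2L, round(period / dt))
    if (np < 2L) stop("period shorter than 2 samples at ", f, " Hz")
    flicker_signal(y, dt, period)
  }, numeric(1))
  out <- data.frame(frequency_hz = frequencies, signal = sig)
  class(out) <- c("freq_response", "data.frame")
  out
}

# steady-state periodic summation: add shifted copies until the central
# window's max/min stabilize to < 0.01%
flicker_signal <- function(y, dt, period_ms) {
  n <- length(y)
  shift <- period_ms / dt                 # samples per period (fractional ok)
  n_copies <- ceiling(n / shift) + 1L
  win0 <- n_copies * shift                # start of central window (samples)
  win_len <- max(3 * shift, 1)
  total_len <- ceiling(win0 + win_len + shift) + n
  acc <- numeric(total_len)
  # every copy overlapping the central window is included, so the window
  # is exactly at steady state: one more copy changes it by nothing
  k <- 0L
  while ((off <- k * shift) <= win0 + win_len) {
    i0 <- floor(off)
    frac <- off - i0
    # linear-interpolated placement for non-integer sample shifts
    idx <- (i0 + 1L):(i0 + n)
    acc[idx] <- acc[idx] + (1 - frac) * y
    if (frac > 0) acc[idx + 1L] <- acc[idx + 1L] + frac * y
    k <- k + 1L
    if (k > 100000L) stop("flicker summation failed to reach steady state")
  }
  w <- acc[(floor(win0) + 1L):floor(win0 + win_len)]
  (max(w) - min(w)) / max(w)
}

#' Hill fit of a frequency response and 3 dB corner frequency
#'
#' Fits the decreasing Hill form \eqn{S(f) = S_0 / (1 + (f/f_h)^n)} to
#' signal-vs-frequency points and returns the 3 dB corner frequency of
#' the fitted curve.
#'
#' Two readings of the corner exist because the flicker "signal" has no
#' dimension fixing what "3 dB" halves. `ref = "half"` (default) takes
#' the frequency where the fitted curve equals \eqn{S_0/2} (which for the
#' Hill form is exactly `f_half`); it reproduces the literature constant
#' of about 730 Hz ms for the reciprocal bandwidth law. `ref = "sqrt2"`
#' takes the amplitude convention \eqn{S_0/\sqrt2}, i.e.
#' \eqn{f_h (\sqrt2 - 1)^{1/n}}.
#'
#' @param freqresp a [flicker_response()] result, or a data.frame with
#'   `frequency_hz` and `signal`.
#' @param ref corner definition, `"half"` (default) or `"sqrt2"`; see
#'   Details.
#' @param monotone_tol tolerated non-monotonicity (fraction of plateau)
#'   before the fit is refused.
#' @return list with `S0`, `f_half`, `exponent`, `f3dB`, `ref`,
#'   `residual_rms`.
#' @export
fit_hill_corner <- function(freqresp, ref = c("half", "sqrt2"),
                            monotone_tol = 0.05) {
  ref <- match.arg(ref)
  f <- freqresp$frequency_hz; sgn <- freqresp$signal
  stopifnot(length(f) >= 4L)
  o <- order(f); f <- f[o]; sgn <- sgn[o]
  if (any(diff(sgn) > monotone_tol * max(sgn)))
    stop("signal increases with frequency beyond tolerance: refusing Hill fit")
  S0 <- max(sgn)
  fh0 <- approx(sgn, f, xout = S0 / 2, ties = "ordered")$y
  if (!is.finite(fh0)) fh0 <- stats::median(f)
  obj <- function(p) {
    S <- exp(p[1]); fh <- exp(p[2]); nn <- exp(p[3])
    sum((sgn - S / (1 + (f / fh)^nn))^2)
  }
  fit <- optim(c(log(S0), log(fh0), log(2)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  S0 <- exp(fit$par[1]); fh <- exp(fit$par[2]); nn <- exp(fit$par[3])
  f3 <- if (ref == "half") fh else fh * (sqrt(2) - 1)^(1 / nn)
  list(S0 = S0, f_half = fh, exponent = nn, f3dB = f3, ref = ref,
       residual_rms = sqrt(fit$value / length(f)))
}

#' Reciprocal bandwidth law
#'
#' Fits the single constant `a` of \eqn{f_{3dB} = a / \mathrm{halfwidth}}
#' by least squares across (half-width, corner frequency) pairs. Across
#' composite responses the constant is about 730 Hz ms.
#'
#' @param halfwidths composite half-widths, ms (> 0).
#' @param f3dBs corner frequencies, Hz (> 0).
#' @return list with `a` (Hz ms), `residual_rms`, `rel_residuals`.
#' @export
fit_reciprocal <- function(halfwidths, f3dBs) {
  stopifnot(length(halfwidths) == length(f3dBs), length(f3dBs) >= 5L,
            all(halfwidths > 0), all(f3dBs > 0))
  if (max(halfwidths) / min(halfwidths) < 3)
    warning("half-widths span less than a 3x range: reciprocal constant ",
            "is poorly constrained")
  x <- 1 / halfwidths
  a <- sum(x * f3dBs) / sum(x * x)        # least squares through the origin
  res <- f3dBs - a * x
  list(a = a, residual_rms = sqrt(mean(res^2)),
       rel_residuals = res / f3dBs)
}
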