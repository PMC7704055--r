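#' Calibrate the composite half-width relation
#'
#' The half-width `b` of a multiphoton composite response exceeds the
#' mean QB half-width `x` because of latency dispersion `a` (the latency
#' SD). For `x/a >= 4` the sum rule `b ~ x + a` holds; below that the
#' sum progressively underestimates `b`. This calibration builds
#' noise-free composites by convolving lognormal QB waveforms with
#' lognormal latency densities over a grid of `x/a` ratios and fits a
#' polynomial map between `b/a` and `x/a`, giving the predictors
#' `predict_x(b, a)` (used when inverting impulse responses) and
#' `predict_b(x, a)`.
#'
#' The polynomial degree is chosen by leave-one-out cross-validation on
#' the calibration grid.
#'
#' @param qb_halfwidths grid of QB half-widths, ms.
#' @param ratios grid of x/a ratios to combine with every half-width.
#' @param latency_cv scatter-to-median ratio of the latency
#'   distributions used in the calibration (the pooled experimental
#'   proportionality is about 0.22).
#' @param halfwidth_cv half-width CV of the QB population each composite
#'   is built from. 0 (default) reproduces the fixed-waveform
#'   construction; 0.23 bakes in the experimental half-width dispersion,
#'   which is the appropriate calibration when inverting impulse
#'   responses generated by variable-width QBs (the mixture of dilated
#'   waveforms is wider than the waveform of the mean width).
#' @param degrees candidate polynomial degrees.
#' @param dt evaluation grid, ms.
#' @return an object of class `halfwidth_relation`: list with the
#'   calibration `grid` (x, a, b), fitted `coefficients` (x/a as a
#'   polynomial in b/a), `degree`, calibrated ranges, and functions
#'   `predict_x(b, a)` and `predict_b(x, a)`.
#' @export
composite_halfwidth_relation <- function(qb_halfwidths = seq(4, 32, by = 4),
                                         ratios = c(0.5, 1, 2, 4, 8, 16),
                                         latency_cv = 0.22,
                                         halfwidth_cv = 0,
                                         degrees = 1:5,
                                         dt = 0.1) {
  stopifnot(length(qb_halfwidths) >= 2L, length(ratios) >= 3L,
            all(qb_halfwidths > 0), all(ratios > 0))
  grid <- expand.grid(x = qb_halfwidths, ratio = ratios)
  grid$a <- grid$x / grid$ratio
  grid$b <- mapply(function(x, a)
    convolved_halfwidth(x, a, latency_cv, dt, halfwidth_cv), grid$x, grid$a)
  q <- grid$b / grid$a                     # predictor
  z <- grid$x / grid$a                     # response
  # leave-one-out CV over candidate degrees
  cv_err <- vapply(degrees, function(d) {
    errs <- vapply(seq_along(q), function(i) {
      fit <- lm(z[-i] ~ poly(q[-i], d, raw = TRUE))
      pr <- sum(coef(fit) * q[i]^(0:d))
      (pr - z[i])^2
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  degree <- degrees[which.min(cv_err)]
  fit <- lm(z ~ poly(q, degree, raw = TRUE))
  cf <- unname(coef(fit))
  # forward map fitted separately (inverting the backward polynomial is
  # ill-conditioned outside the data range)
  fwd <- lm(I(grid$b / grid$a) ~ poly(z, degree, raw = TRUE))
  cf_fwd <- unname(coef(fwd))
  q_range <- range(q)
  xa_range <- range(z)
  poly_eval <- function(v) vapply(v, function(u) sum(cf * u^(0:degree)),
                                  numeric(1))
  poly_fwd <- function(v) vapply(v, function(u) sum(cf_fwd * u^(0:degree)),
                                 numeric(1))
  predict_x <- function(b, a) {
    if (any(a < 0) || any(b <= 0)) stop("b must be positive, a non-negative")
    out <- numeric(length(b))
    a <- rep_len(a, length(b))
    for (i in seq_along(b)) {
      if (a[i] == 0) { out[i] <- b[i]; next }  # no dispersion: b = x
      qi <- b[i] / a[i]
      if (qi < q_range[1] || qi > q_range[2])
        warning("b/a = ", signif(qi, 3),
                " outside the calibrated range [",
                signif(q_range[1], 3), ", ", signif(q_range[2], 3),
                "]: extrapolating")
      out[i] <- a[i] * poly_eval(qi)
    }
    out
  }
  predict_b <- function(x, a) {
    if (any(a < 0) || any(x <= 0)) stop("x must be positive, a non-negative")
    out <- numeric(length(x))
    a <- rep_len(a, length(x))
    for (i in seq_along(x)) {
      if (a[i] == 0) { out[i] <- x[i]; next }
      zi <- x[i] / a[i]
      if (zi < xa_range[1] || zi > xa_range[2]) {
        warning("x/a = ", signif(zi, 3), " outside the calibrated range: ",
                "extrapolating")
        # beyond the plateau the sum rule is exact to the fit resolution
        out[i] <- if (zi > xa_range[2]) x[i] + a[i] else a[i] * poly_fwd(zi)
        next
      }
      out[i] <- a[i] * poly_fwd(zi)
    }
    out
  }
  structure(list(grid = grid, coefficients = cf, degree = degree,
                 cv_error = cv_err, q_range = q_range, xa_range = xa_range,
                 latency_cv = latency_cv, halfwidth_cv = halfwidth_cv,
                 predict_x = predict_x, predict_b = predict_b),
            class = "halfwidth_relation")
}

#' @export
print.halfwidth_relation <- function(x, ...) {
  cat(sprintf(
    "<halfwidth_relation> degree-%d polynomial x/a ~ b/a over b/a in [%.2f, %.2f]\n",
    x$degree, x$q_range[1], x$q_range[2]))
  cat("  coefficients:", signif(x$coefficients, 4), "\n")
  invisible(x)
}

# half-width of the dense convolution of a lognormal QB (half-width x,
# unit amplitude; optionally a normal mixture of time-dilated copies at
# CV `halfwidth_cv`) with a lognormal latency density of SD `a` and
# scatter/median ratio latency_cv
convolved_halfwidth <- function(x, a, latency_cv = 0.22, dt = 0.1,
                                halfwidth_cv = 0) {
  qb <- gen_lognormal_qb(x, amplitude = 1)
  t_end0 <- max(waveform_grid(qb)) * (1 + 3 * halfwidth_cv)
  if (a > 0) {
    med <- a / latency_cv
    sigma <- asinh(latency_cv)
    t_end <- med * exp(3.5 * sigma) + t_end0 + 5
  } else t_end <- t_end0 + 5
  t <- seq(0, t_end, by = dt)
  y <- mixture_waveform(qb, t, halfwidth_cv)
  if (a > 0) {
    dens <- dlnorm(t, meanlog = log(med), sdlog = sigma)
    y <- convolve_causal(y, dens * dt)[seq_along(t)]
  }
  f <- suppressWarnings(extract_features(y, time = t))
  f$half_width
}

# expectation over normal time-dilation factors (amplitude preserved),
# via a 15-node quantile rule on the truncated dilation distribution
mixture_waveform <- function(qb, t, halfwidth_cv) {
  if (halfwidth_cv == 0) return(eval_waveform(qb, t))
  pr <- (seq_len(15) - 0.5) / 15
  s <- pmax(qnorm(pr, 1, halfwidth_cv), 0.05)
  acc <- numeric(length(t))
  for (si in s) acc <- acc + eval_waveform(qb, t / si)
  acc / length(s)
}

convolve_causal <- function(y, k) {
  n <- length(y) + length(k) - 1L
  m <- stats::nextn(n, 2)
  fy <- stats::fft(c(y, numeric(m - length(y))))
  fk <- stats::fft(c(k, numeric(m - length(k))))
  Re(stats::fft(fy * fk, inverse = TRUE))[1:n] / m
}
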