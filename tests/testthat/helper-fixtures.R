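# Shared fixtures, all built in code.

# isoceles triangular pulse: peak `amp` at t_peak, rising from
# t_peak - half_base, back to baseline at t_peak + half_base
triangle_trace <- function(amp = -50, t_peak = 30, half_base = 10,
                           dt = 0.05, t_end = 60) {
  t <- seq(0, t_end, by = dt)
  y <- amp * pmax(0, 1 - abs(t - t_peak) / half_base)
  data.frame(time_ms = t, current_pA = y)
}

# dense-grid brute-force feature oracle: nearest-sample crossings on a
# 10 us grid, no interpolation
brute_features <- function(wf, dt = 0.01) {
  t <- seq(dt, wf$t_peak * 8, by = dt)
  y <- abs(eval_waveform(wf, t))
  A <- max(y); pk <- which.max(y)
  first_at <- function(level) t[which(y >= level)[1]]
  rise_at <- function(level) {
    i <- which(y[seq_len(pk)] >= level)[1]; t[i]
  }
  fall_at <- function(level) {
    i <- pk + which(y[pk:length(y)] < level)[1] - 1L; t[i]
  }
  list(latency10 = first_at(0.1 * A),
       half_width = fall_at(0.5 * A) - rise_at(0.5 * A),
       rise_20_80 = rise_at(0.8 * A) - rise_at(0.2 * A))
}

# closed-form periodic-summation (Poisson summation) signal for a
# Gaussian pulse of the given FWHM
gauss_flicker_oracle <- function(fwhm_ms, f_hz) {
  sig <- fwhm_ms / (2 * sqrt(2 * log(2))) / 1000
  Tp <- 1 / f_hz
  ks <- 1:80
  coef <- exp(-2 * pi^2 * ks^2 * sig^2 / Tp^2)
  tt <- seq(0, Tp, length.out = 801)
  v <- vapply(tt, function(t0) 1 + 2 * sum(coef * cos(2 * pi * ks * t0 / Tp)),
              numeric(1))
  (max(v) - min(v)) / max(v)
}

# cached control ensemble shared across test files that need one
control_ensemble <- local({
  cache <- NULL
  function(n_trials = 200L, seed = 11L) {
    if (is.null(cache))
      cache <<- run_ensemble(make_control_params(), n_trials = n_trials,
                             seed = seed)
    cache
  }
})

# small latency sampler factory (lognormal via median/scatter)
lat_sampler <- function(median, scatter) {
  if (scatter == 0) return(function(k) rep(median, k))
  sg <- asinh(scatter / median)
  function(k) stats::rlnorm(k, log(median), sg)
}
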