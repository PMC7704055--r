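#' Lognormal latency samples
#'
#' Draws `n` latencies from a lognormal distribution parameterized the
#' way latency statistics are reported: by the median and the scatter
#' \eqn{(\mu e^{\sigma} - \mu e^{-\sigma})/2}. The log-SD follows as
#' \eqn{\sigma = \mathrm{asinh}(\mathrm{scatter}/\mathrm{median})};
#' feasibility requires `scatter < median * sinh(1)` (sigma < 1).
#'
#' @param median lognormal median, ms (> 0).
#' @param scatter scatter, ms (>= 0); 0 gives a degenerate sample.
#' @param n sample size.
#' @param seed integer seed.
#' @return numeric vector of `n` positive latencies.
#' @export
gen_latency_samples <- function(median, scatter, n, seed) {
  stopifnot(median > 0, scatter >= 0, n >= 1L)
  if (scatter >= median * sinh(1))
    stop("scatter ", scatter, " infeasible for median ", median,
         " (requires scatter < median * sinh(1) = ", signif(median * sinh(1), 4), ")")
  if (scatter == 0) return(rep(median, n))
  sigma <- asinh(scatter / median)
  with_seed(seed, rlnorm(n, meanlog = log(median), sdlog = sigma))
}

#' Specification of a synthetic QB population
#'
#' Describes the statistical structure the analysis assumes: lognormal
#' latencies (median + scatter), normally distributed half-width dilation
#' factors (mean half-width + CV) and normally distributed amplitude
#' scale factors (mean amplitude + CV, truncated at 0.05 to avoid sign
#' flips).
#'
#' @param median_latency ms.
#' @param latency_scatter ms.
#' @param mean_half_width ms.
#' @param half_width_cv dimensionless (>= 0); default 0.23, the pooled
#'   experimental proportionality.
#' @param mean_amplitude peak amplitude (negative for current).
#' @param amplitude_cv dimensionless (>= 0).
#' @param t_peak_ratio waveform peak time as a multiple of half-width.
#' @return an object of class `qb_population_spec`.
#' @export
qb_population_spec <- function(median_latency = 30, latency_scatter = 6.6,
                               mean_half_width = 20, half_width_cv = 0.23,
                               mean_amplitude = -1, amplitude_cv = 0.3,
                               t_peak_ratio = 1.5) {
  stopifnot(median_latency > 0, latency_scatter >= 0, mean_half_width > 0,
            half_width_cv >= 0, mean_amplitude != 0, amplitude_cv >= 0,
            t_peak_ratio > 0)
  structure(list(median_latency = median_latency,
                 latency_scatter = latency_scatter,
                 mean_half_width = mean_half_width,
                 half_width_cv = half_width_cv,
                 mean_amplitude = mean_amplitude,
                 amplitude_cv = amplitude_cv,
                 t_peak_ratio = t_peak_ratio),
            class = "qb_population_spec")
}

#' Generate a synthetic QB population
#'
#' Produces `n` quantum bumps from a [qb_population_spec()]: a base
#' lognormal waveform dilated along the time axis by normal factors
#' (half-width variability, amplitude preserved), scaled vertically by
#' normal factors truncated at 0.05 (amplitude variability), and paired
#' with lognormal latencies.
#'
#' @param spec a [qb_population_spec()].
#' @param n population size.
#' @param seed integer seed.
#' @return list with `waveforms` (list of [lognormal_waveform()]) and
#'   `latencies` (numeric vector, ms).
#' @export
gen_qb_population <- function(spec, n, seed) {
  stopifnot(inherits(spec, "qb_population_spec"), n >= 1L)
  with_seed(seed, {
    lat <- gen_latency_samples(spec$median_latency, spec$latency_scatter, n,
                               seed = NULL)
    hw_f <- pmax(rnorm(n, 1, spec$half_width_cv), 0.05)
    am_f <- pmax(rnorm(n, 1, spec$amplitude_cv), 0.05)
    wfs <- lapply(seq_len(n), function(i) {
      h <- spec$mean_half_width * hw_f[i]
      gen_lognormal_qb(h, amplitude = spec$mean_amplitude * am_f[i],
                       t_peak = spec$t_peak_ratio * h)
    })
    list(waveforms = wfs, latencies = lat)
  })
}

#' Synthesize a multiphoton impulse response
#'
#' Builds one composite response from `n_qbs` population draws
#' (optionally Poisson-distributed for photon noise), optionally applies
#' single-pole membrane filtering, and measures its 10% latency and
#' half-width — the two quantities the extraction algorithm consumes.
#'
#' @param spec a [qb_population_spec()].
#' @param n_qbs QB count (Poisson mean when `photon = TRUE`).
#' @param photon draw the QB count from a Poisson distribution.
#' @param rc_tau optional membrane time constant, ms (`NULL` = no
#'   filtering).
#' @param seed integer seed.
#' @param dt grid step, ms.
#' @return list with `trace` (data.frame `time_ms`, `value`) and `spec`
#'   (one-row data.frame of class `impulse_response_spec` with
#'   `latency10` and `half_width`, ms).
#' @export
gen_impulse_response <- function(spec, n_qbs = 100L, photon = FALSE,
                                 rc_tau = NULL, seed = 1L, dt = 0.25) {
  stopifnot(inherits(spec, "qb_population_spec"))
  with_seed(seed, {
    pop_seed <- NULL
    lat_sampler <- function(k)
      if (spec$latency_scatter == 0) rep(spec$median_latency, k)
      else rlnorm(k, log(spec$median_latency),
                  asinh(spec$latency_scatter / spec$median_latency))
    qb_src <- function(k) {
      hw_f <- pmax(rnorm(k, 1, spec$half_width_cv), 0.05)
      am_f <- pmax(rnorm(k, 1, spec$amplitude_cv), 0.05)
      lapply(seq_len(k), function(i) {
        h <- spec$mean_half_width * hw_f[i]
        gen_lognormal_qb(h, amplitude = spec$mean_amplitude * am_f[i],
                         t_peak = spec$t_peak_ratio * h)
      })
    }
    n_draw <- if (photon) function(m) rpois(m, n_qbs) else n_qbs
    cs <- build_composite(qb_src, n_draw, lat_sampler, n_members = 1L,
                          seed = NULL, dt = dt, allow_empty = photon)
    tr <- data.frame(time_ms = cs$time, value = cs$average)
    if (!is.null(rc_tau)) tr <- rc_filter(tr, rc_tau)
    fe <- suppressWarnings(extract_features(tr))
    ir <- impulse_response_spec(latency10 = fe$latency10,
                                half_width = fe$half_width)
    list(trace = tr, spec = ir)
  })
}

#' Impulse-response summary used by the extraction algorithm
#'
#' @param latency10 10%-rise latency of the impulse response, ms (> 0).
#' @param half_width half-width of the impulse response, ms (> 0).
#' @param adaptation free-text label (e.g. "dark-adapted").
#' @return one-row data.frame of class `impulse_response_spec`.
#' @export
impulse_response_spec <- function(latency10, half_width, adaptation = "") {
  stopifnot(latency10 > 0, half_width > 0)
  out <- data.frame(latency10 = latency10, half_width = half_width,
                    adaptation = adaptation)
  class(out) <- c("impulse_response_spec", "data.frame")
  out
}
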