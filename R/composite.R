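#' Aligned average bump
#'
#' Time-shifts single-bump traces so their rising-phase crossings at
#' `align_fraction` of each bump's own peak coincide, then averages
#' pointwise. Alignment removes latency dispersion, so the aligned
#' average is narrower than the unaligned ("composite") average whenever
#' latency SD is positive.
#'
#' @param traces list of single-bump traces (`bump_trace` objects or
#'   data.frames with `time_ms` and `current_pA`/`value`).
#' @param align_fraction rising-phase alignment level as a fraction of
#'   each peak (default 0.1).
#' @param dt output grid step, ms; defaults to the grid of the first
#'   trace.
#' @return data.frame with `time_ms` and `value` (the average trace);
#'   time 0 corresponds to the mean alignment point.
#' @export
average_bump <- function(traces, align_fraction = 0.1, dt = NULL) {
  stopifnot(length(traces) >= 2L)
  xs <- lapply(traces, as_trace_xy)
  if (is.null(dt)) dt <- diff(xs[[1]]$t[1:2])
  marks <- vapply(xs, function(tr) {
    u <- abs(tr$y)
    m <- first_crossing(tr$t, u, align_fraction * max(u))
    if (!is.finite(m)) stop("trace without a ", align_fraction * 100,
                            "% rising crossing cannot be aligned")
    m
  }, numeric(1))
  ref <- mean(marks)
  spans <- vapply(xs, function(tr) range(tr$t), numeric(2))
  t_out <- seq(min(spans[1, ] - marks + ref), max(spans[2, ] - marks + ref),
               by = dt)
  acc <- numeric(length(t_out))
  for (i in seq_along(xs)) {
    sh <- approx(xs[[i]]$t - marks[i] + ref, xs[[i]]$y, xout = t_out,
                 yleft = 0, yright = 0)$y
    acc <- acc + sh
  }
  data.frame(time_ms = t_out, value = acc / length(xs))
}

#' Build a set of multiphoton composite responses
#'
#' Each member of the set is the sum of `n` latency-shifted quantum
#' bumps, the in-silico analog of a multiphoton impulse response. The
#' average trace is the "signal"; the pointwise SD trace across members
#' is the basis of the area-based noise measure.
#'
#' @param qb_source the QB supply: a list of traces, a list of
#'   [lognormal_waveform()] objects, a single waveform, or a function
#'   `function(k)` returning `k` waveforms.
#' @param n_qbs integer QB count per member, or a function `function(m)`
#'   returning `m` counts (e.g. Poisson draws for photon noise). Zero
#'   counts are allowed only when `allow_empty = TRUE` and produce flat
#'   members.
#' @param latency_sampler function `function(k)` returning `k`
#'   non-negative latency shifts in ms (e.g. from
#'   [gen_latency_samples()]).
#' @param n_members number of composite responses.
#' @param seed integer seed.
#' @param dt time grid step, ms.
#' @param t_max end of the time grid, ms; chosen from the QB source and
#'   latency scale when `NULL`.
#' @param allow_empty allow members with zero QBs (photon-noise mode).
#' @return an object of class `composite_set`: list with `time`,
#'   `members` (matrix, one column per member), `n_qbs` (per member),
#'   `average`, `sd_trace`, `mad_trace`.
#' @export
build_composite <- function(qb_source, n_qbs, latency_sampler, n_members,
                            seed, dt = 0.5, t_max = NULL,
                            allow_empty = FALSE) {
  stopifnot(n_members >= 1L)
  draw_qbs <- qb_drawer(qb_source)
  with_seed(seed, {
    counts <- if (is.function(n_qbs)) n_qbs(n_members)
              else rep(as.integer(n_qbs), n_members)
    if (any(counts < 0)) stop("negative QB count")
    if (any(counts == 0) && !allow_empty)
      stop("zero-QB members are only allowed with allow_empty = TRUE ",
           "(photon-noise mode)")
    if (is.null(t_max)) {
      probe_l <- latency_sampler(200L)
      t_max <- max(probe_l) + qb_span(qb_source) * 1.5
    }
    t <- seq(0, t_max, by = dt)
    members <- matrix(0, nrow = length(t), ncol = n_members)
    for (m in seq_len(n_members)) {
      k <- counts[m]
      if (k == 0L) next
      lats <- latency_sampler(k)
      if (any(lats < 0)) stop("latency sampler returned negative shifts")
      qbs <- draw_qbs(k)
      acc <- numeric(length(t))
      for (j in seq_len(k)) acc <- acc + eval_qb_at(qbs[[j]], t - lats[j])
      members[, m] <- acc
    }
    avg <- rowMeans(members)
    sdv <- apply(members, 1L, sd)
    madv <- rowMeans(abs(members - avg))
    structure(list(time = t, members = members, n_qbs = counts,
                   average = avg, sd_trace = sdv, mad_trace = madv,
                   seed = as.integer(seed)),
              class = "composite_set")
  })
}

#' @export
print.composite_set <- function(x, ...) {
  cat(sprintf("<composite_set> %d members, %s QBs each, %d samples (dt %g ms)\n",
              ncol(x$members),
              if (length(unique(x$n_qbs)) == 1L) x$n_qbs[1]
              else sprintf("%d-%d", min(x$n_qbs), max(x$n_qbs)),
              length(x$time), diff(x$time[1:2])))
  invisible(x)
}

# normalize the many accepted QB source forms to function(k) -> list
qb_drawer <- function(qb_source) {
  if (inherits(qb_source, "lognormal_waveform")) {
    src <- list(qb_source)
  } else if (is.function(qb_source)) {
    return(function(k) qb_source(k))
  } else if (is.list(qb_source)) {
    src <- qb_source
  } else stop("unsupported qb_source")
  function(k) src[sample.int(length(src), k, replace = TRUE)]
}

eval_qb_at <- function(qb, t) {
  if (inherits(qb, "lognormal_waveform")) return(eval_waveform(qb, t))
  tr <- as_trace_xy(qb)
  approx(tr$t, tr$y, xout = t, yleft = 0, yright = 0)$y
}

qb_span <- function(qb_source) {
  one <- if (inherits(qb_source, "lognormal_waveform")) qb_source
         else if (is.function(qb_source)) qb_source(1L)[[1]]
         else qb_source[[1]]
  if (inherits(one, "lognormal_waveform"))
    return(max(waveform_grid(one, tail_frac = 0.001)))
  max(as_trace_xy(one)$t)
}

#' Fit a lognormal waveform to a trace
#'
#' Least-squares fit of \eqn{A \exp(-[\ln(t/t_p)]^2 / 2w^2)} to a
#' single-peaked trace; the standard smooth description of average bumps
#' and impulse responses. The fit is seeded from the measured peak and
#' half-width and refined by Nelder-Mead.
#'
#' @param trace a trace (data.frame, `bump_trace`, or numeric with
#'   `time`).
#' @param time optional time vector for numeric input.
#' @return a [lognormal_waveform()] with attributes `rms` (residual RMS)
#'   and `rel_rms` (RMS / |A|).
#' @export
fit_lognormal_waveform <- function(trace, time = NULL) {
  tr <- as_trace_xy(trace, time)
  t <- tr$t; y <- tr$y
  pk <- which.max(abs(y))
  s <- sign(y[pk])
  A0 <- y[pk]; tp0 <- t[pk]
  if (tp0 <= 0) stop("peak at non-positive time: cannot fit lognormal form")
  fe <- extract_features(tr$y, time = tr$t)
  w0 <- asinh(fe$half_width / (2 * tp0)) / sqrt(2 * log(2))
  obj <- function(p) {
    wf <- list(amplitude = p[1], t_peak = exp(p[2]), shape = exp(p[3]))
    class(wf) <- "lognormal_waveform"
    sum((y - eval_waveform(wf, t))^2)
  }
  fit <- optim(c(A0, log(tp0), log(w0)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  if (fit$convergence != 0)
    stop("lognormal waveform fit did not converge (code ", fit$convergence,
         "); peak ", signif(A0, 3), " at ", signif(tp0, 3), " ms")
  wf <- lognormal_waveform(fit$par[1], exp(fit$par[2]), exp(fit$par[3]))
  rms <- sqrt(fit$value / length(y))
  attr(wf, "rms") <- rms
  attr(wf, "rel_rms") <- rms / abs(wf$amplitude)
  wf
}

#' Single-pole RC low-pass filter
#'
#' Membrane stand-in: convolves a current trace with an exponential
#' kernel of time constant `tau` (unit DC gain). The output is always at
#' least as wide as the input; `tau -> 0` returns the input.
#'
#' @param trace a trace (data.frame with `time_ms` + value column, or
#'   numeric with `time`).
#' @param tau membrane time constant, ms (> 0; 0 allowed as identity).
#' @param time optional time vector for numeric input.
#' @return data.frame with `time_ms`, `value`.
#' @export
rc_filter <- function(trace, tau, time = NULL) {
  stopifnot(is.numeric(tau), length(tau) == 1L, tau >= 0)
  tr <- as_trace_xy(trace, time)
  if (tau == 0) return(data.frame(time_ms = tr$t, value = tr$y))
  dt <- diff(tr$t[1:2])
  a <- 1 - exp(-dt / tau)
  v <- as.numeric(stats::filter(a * tr$y, 1 - a, method = "recursive"))
  data.frame(time_ms = tr$t, value = v)
}
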