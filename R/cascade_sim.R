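#' Simulate one quantum bump
#'
#' Runs the stochastic single-microvillus cascade for one photon
#' absorption at t = 0 and returns the molecular time courses and the
#' resulting current. Identical `(params, seed)` pairs reproduce the
#' identical trace bit-for-bit.
#'
#' @param params a [cascade_params()] object.
#' @param seed integer seed (required; every stochastic operation in the
#'   package takes an explicit seed).
#' @param check_decay if `TRUE` (default), warn when the current has not
#'   returned within 1% of baseline by the end of the simulated window.
#' @return an object of class `bump_trace`: list with `time` (ms),
#'   `current` (pA, <= 0), integer count vectors `n_Ga`, `n_GaPLC`,
#'   `n_DAG`, `n_open`, the `seed` and the `params` used.
#' @export
simulate_bump <- function(params, seed, check_decay = TRUE) {
  validate_cascade_params(params)
  if (missing(seed)) stop("simulate_bump() requires an explicit seed")
  n_steps <- as.integer(ceiling(params$duration / params$dt)) + 1L
  if (n_steps < 3L) stop("duration must cover at least two steps")
  k <- params$kinetics
  cpar <- list(
    dt = params$dt, n_steps = n_steps,
    k_exch = params$gdp_gtp_exchange_rate,
    g_total = as.integer(round(k$g_pool0 * params$gq_fraction / 100)),
    g_pool0 = k$g_pool0,
    plc_total = as.integer(round(k$plc_pool0 * params$plc_fraction / 100)),
    plc_pool0 = k$plc_pool0,
    k_bind = params$diffusion_params$k_bind,
    k_ga_loss = k$k_ga_loss, k_m = k$k_m, k_gap = k$k_gap,
    k_hyd = params$pip2_breakdown_rate, pip2_total = as.integer(k$pip2_total),
    k_ddeg = k$k_ddeg, k_open = k$k_open, k_close = k$k_close,
    dag_k = k$dag_k, hill = k$hill,
    sens = params$channel_sensitivity, n_channels = params$n_channels,
    ca_in = k$ca_in, tau_ca = k$tau_ca, ca_open = k$ca_open,
    ca_close = k$ca_close, ca_gap = k$ca_gap, ca_m = k$ca_m,
    ca_half = k$ca_half,
    ca_ddeg = k$ca_ddeg,
    pkc = params$pkc_activity_factor, pkc_w = k$pkc_w)
  res <- with_seed(seed, simulate_bump_cpp(cpar))
  tr <- structure(list(
    time = seq(0, by = params$dt, length.out = n_steps),
    current = params$single_channel_current * res$n_open,
    n_Ga = res$n_Ga, n_GaPLC = res$n_GaPLC, n_DAG = res$n_DAG,
    n_open = res$n_open,
    seed = as.integer(seed), params = params), class = "bump_trace")
  if (check_decay) {
    pk <- max(abs(tr$current))
    tail_mag <- abs(tr$current[length(tr$current)])
    if (pk > 0 && tail_mag > 0.01 * pk)
      warning(warningCondition(
        "current has not returned within 1% of baseline: increase `duration`",
        class = "microbump_truncated_bump"))
  }
  tr
}

#' @export
print.bump_trace <- function(x, ...) {
  cat(sprintf("<bump_trace> %d samples, dt %g ms, peak %.4g pA (seed %d)\n",
              length(x$time), x$params$dt, min(x$current), x$seed))
  invisible(x)
}

#' @export
as.data.frame.bump_trace <- function(x, ...) {
  data.frame(time_ms = x$time, current_pA = x$current, n_Ga = x$n_Ga,
             n_GaPLC = x$n_GaPLC, n_DAG = x$n_DAG, n_open = x$n_open)
}

#' Simulate an ensemble of quantum bumps
#'
#' Runs `n_trials` independent single-photon simulations with per-trial
#' sub-seeds derived from the master seed, and flags the traces whose
#' peak magnitude exceeds the amplitude threshold as bumps. Only
#' supra-threshold traces enter downstream statistics; averaging the
#' zero-bump trials is the standard quality control (it must give a flat
#' trace).
#'
#' @param params a [cascade_params()] object.
#' @param n_trials number of independent photon-absorption trials.
#' @param threshold amplitude threshold, pA (negative; default -7 pA).
#' @param seed master integer seed.
#' @return an object of class `bump_ensemble`: list with `traces`,
#'   logical `is_bump`, `n_trials`, `n_bumps`, `bump_probability`,
#'   `amplitude_threshold`, `params`, `seed`.
#' @export
run_ensemble <- function(params, n_trials = 200L, threshold = -7, seed = 1L) {
  validate_cascade_params(params)
  stopifnot(n_trials >= 1L)
  if (threshold >= 0)
    stop("threshold must be negative, matching the inward-current sign")
  traces <- vector("list", n_trials)
  is_bump <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    traces[[i]] <- simulate_bump(params, seed = sub_seed(seed, i),
                                 check_decay = FALSE)
    is_bump[i] <- min(traces[[i]]$current) < threshold
  }
  structure(list(traces = traces, is_bump = is_bump,
                 n_trials = as.integer(n_trials),
                 n_bumps = sum(is_bump),
                 bump_probability = mean(is_bump),
                 amplitude_threshold = threshold,
                 params = params, seed = as.integer(seed)),
            class = "bump_ensemble")
}

#' @export
print.bump_ensemble <- function(x, ...) {
  cat(sprintf("<bump_ensemble> %d / %d trials above %g pA (P = %.2f)\n",
              x$n_bumps, x$n_trials, x$amplitude_threshold,
              x$bump_probability))
  invisible(x)
}

#' Feature table of the supra-threshold bumps in an ensemble
#'
#' @param ensemble a [run_ensemble()] result.
#' @return data.frame of per-bump features (one row per supra-threshold
#'   trace), with the trial index in column `trial`.
#' @export
ensemble_features <- function(ensemble) {
  stopifnot(inherits(ensemble, "bump_ensemble"))
  idx <- which(ensemble$is_bump)
  rows <- lapply(idx, function(i) {
    # stochastic traces routinely re-cross the 50% level; the outermost
    # rule handles that, so the per-trace warning is muffled here
    f <- try(withCallingHandlers(
      extract_features(ensemble$traces[[i]]),
      microbump_ambiguous_halfwidth = function(w)
        invokeRestart("muffleWarning")), silent = TRUE)
    if (inherits(f, "try-error")) return(NULL)
    f$trial <- i
    f
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop("no measurable bumps in ensemble")
  out
}

#' Molecular peak summary of one trace
#'
#' Per-species maximum count and time of the *first* maximum (plateaus
#' and double peaks resolve to the earliest time attaining the maximum),
#' for active Galpha, Galpha-PLC and DAG.
#'
#' @param trace a `bump_trace` (or any list with `time` and the three
#'   count vectors).
#' @return one-row data.frame with `Nmax_Ga`, `t_Nmax_Ga`, `Nmax_GaPLC`,
#'   `t_Nmax_GaPLC`, `Nmax_DAG`, `t_Nmax_DAG`.
#' @export
molecular_peaks <- function(trace) {
  pk <- function(v, nm) {
    if (all(v == 0))
      stop("all-zero ", nm, " time course: peak undefined")
    i <- which.max(v)                    # which.max returns the first max
    c(max = v[i], t = trace$time[i])
  }
  ga <- pk(trace$n_Ga, "Galpha"); gp <- pk(trace$n_GaPLC, "Galpha-PLC")
  dg <- pk(trace$n_DAG, "DAG")
  data.frame(Nmax_Ga = ga["max"], t_Nmax_Ga = ga["t"],
             Nmax_GaPLC = gp["max"], t_Nmax_GaPLC = gp["t"],
             Nmax_DAG = dg["max"], t_Nmax_DAG = dg["t"],
             row.names = NULL)
}

#' Normalized 20-80% rise slope of the DAG time course
#'
#' Slope of the peak-normalized DAG accumulation curve between 20% and
#' 80% of its maximum, in 1/ms. Faster cascades show steeper DAG rises.
#'
#' @param trace a `bump_trace`.
#' @return slope in ms^-1.
#' @export
dag_rise_slope <- function(trace) {
  v <- trace$n_DAG
  if (max(v) < 1) stop("DAG peak below resolution: slope undefined")
  u <- v / max(v)
  pk <- which.max(v)
  t20 <- rising_crossing(trace$time, u, 0.2, pk)
  t80 <- rising_crossing(trace$time, u, 0.8, pk)
  if (!is.finite(t20) || !is.finite(t80) || t80 <= t20)
    stop("DAG rise crossings undefined")
  0.6 / (t80 - t20)
}

#' Unaligned ensemble-average trace
#'
#' Averages the selected traces without alignment (the construction used
#' for the "composite QB current" and the average molecular curves in the
#' parametric analysis).
#'
#' @param ensemble a `bump_ensemble`.
#' @param which_traces `"bumps"` (default), `"failures"`, or `"all"`.
#' @return data.frame with `time_ms`, `current_pA`, `n_Ga`, `n_GaPLC`,
#'   `n_DAG`, `n_open` (means across trials).
#' @export
ensemble_average <- function(ensemble,
                             which_traces = c("bumps", "failures", "all")) {
  which_traces <- match.arg(which_traces)
  sel <- switch(which_traces,
                bumps = which(ensemble$is_bump),
                failures = which(!ensemble$is_bump),
                all = seq_len(ensemble$n_trials))
  if (!length(sel)) stop("no traces in selection '", which_traces, "'")
  avg <- function(field) {
    m <- vapply(sel, function(i) as.numeric(ensemble$traces[[i]][[field]]),
                numeric(length(ensemble$traces[[1]]$time)))
    rowMeans(m)
  }
  data.frame(time_ms = ensemble$traces[[1]]$time,
             current_pA = avg("current"), n_Ga = avg("n_Ga"),
             n_GaPLC = avg("n_GaPLC"), n_DAG = avg("n_DAG"),
             n_open = avg("n_open"))
}
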