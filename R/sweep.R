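#' Default parametric sweep grid
#'
#' The five activation-parameter families with their printed ranges:
#' GDP-to-GTP exchange 125-1000 s^-1 (1-8 ms per event in 1 ms steps),
#' Gq and PLC availability 10-300% (log-spaced, containing the control
#' 100%), PIP2 breakdown 500-10000 s^-1 (0.1-2 ms per event in 0.2 ms
#' steps), and channel sensitivity to DAG 0.15-0.8. Every family
#' contains its control value.
#'
#' @return named list mapping parameter name to its value grid.
#' @export
default_sweep_grid <- function() {
  list(
    gdp_gtp_exchange_rate = c(1000, 500, 333, 250, 200, 167, 143, 125),
    gq_fraction = c(10, 20, 35, 60, 100, 160, 230, 300),
    plc_fraction = c(10, 20, 35, 60, 100, 160, 230, 300),
    pip2_breakdown_rate = c(10000, 3333, 2000, 1428, 1111, 909, 769, 667,
                            588, 526, 500),
    channel_sensitivity = c(0.15, 0.2, 0.25, 0.3, 0.34, 0.45, 0.6, 0.8)
  )
}

control_value <- function(parameter) {
  ctrl <- make_control_params()
  ctrl[[parameter]]
}

#' Run a parametric sweep of the cascade
#'
#' Simulates an ensemble for every (parameter, value) setting of the
#' grid, collects ensemble statistics of the supra-threshold bumps,
#' unaligned-average molecular peak summaries, the DAG rise slope of the
#' average cascade, and the half-width and 10% latency of the unaligned
#' composite average current. Settings with fewer than `min_bumps`
#' measurable bumps are flagged and excluded from downstream regressions
#' and correlations.
#'
#' @param grid a grid as returned by [default_sweep_grid()] (possibly a
#'   subset).
#' @param n_trials photon trials per setting (200 full scale; 60 is the
#'   reduced CI mode).
#' @param threshold bump amplitude threshold, pA.
#' @param seed master seed.
#' @param base_params baseline [cascade_params()] modified one parameter
#'   at a time.
#' @param min_bumps flag floor (20).
#' @return data.frame of class `sweep_table`: one row per setting.
#' @export
run_sweep <- function(grid = default_sweep_grid(), n_trials = 200L,
                      threshold = -7, seed = 1L,
                      base_params = make_control_params(),
                      min_bumps = 20L) {
  stopifnot(is.list(grid), length(grid) >= 1L)
  rows <- list(); idx <- 0L
  for (fam in names(grid)) {
    if (!fam %in% names(unclass(base_params)))
      stop("unknown sweep parameter: ", fam)
    for (val in grid[[fam]]) {
      idx <- idx + 1L
      pars <- base_params
      pars[[fam]] <- val
      validate_cascade_params(pars)
      ens <- run_ensemble(pars, n_trials = n_trials, threshold = threshold,
                          seed = sub_seed(seed, idx))
      row <- sweep_row(fam, val, ens, min_bumps)
      row$is_control <- isTRUE(all.equal(val, control_value(fam)))
      rows[[idx]] <- row
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_table", "data.frame")
  out
}

sweep_row <- function(fam, val, ens, min_bumps) {
  empty_stats <- data.frame(
    n = 0L, median_latency = NA_real_, mean_latency = NA_real_,
    latency_scatter = NA_real_, latency_sd = NA_real_,
    latency_sigma = NA_real_, mean_amplitude = NA_real_,
    amplitude_sd = NA_real_, amplitude_cv = NA_real_,
    mean_half_width = NA_real_, half_width_sd = NA_real_,
    half_width_cv = NA_real_, mean_rise_slope = NA_real_)
  base <- data.frame(parameter = fam, value = val, n_trials = ens$n_trials,
                     n_bumps = ens$n_bumps)
  flagged <- ens$n_bumps < min_bumps
  if (flagged) {
    st <- empty_stats
    mol <- data.frame(Nmax_Ga = NA_real_, t_Nmax_Ga = NA_real_,
                      Nmax_GaPLC = NA_real_, t_Nmax_GaPLC = NA_real_,
                      Nmax_DAG = NA_real_, t_Nmax_DAG = NA_real_)
    extra <- data.frame(dag_slope = NA_real_, comp_half_width = NA_real_,
                        comp_latency10 = NA_real_)
  } else {
    fe <- suppressWarnings(ensemble_features(ens))
    st <- suppressWarnings(ensemble_stats(fe))
    avg <- ensemble_average(ens, "bumps")
    avg_tr <- list(time = avg$time_ms, n_Ga = avg$n_Ga,
                   n_GaPLC = avg$n_GaPLC, n_DAG = avg$n_DAG)
    mol <- molecular_peaks(avg_tr)
    ds <- tryCatch(dag_rise_slope(avg_tr), error = function(e) NA_real_)
    cf <- tryCatch(
      suppressWarnings(extract_features(avg$current_pA, time = avg$time_ms)),
      error = function(e) NULL)
    extra <- data.frame(
      dag_slope = ds,
      comp_half_width = if (is.null(cf)) NA_real_ else cf$half_width,
      comp_latency10 = if (is.null(cf)) NA_real_ else cf$latency10)
    flagged <- nrow(fe) < min_bumps      # features can be fewer than bumps
  }
  cbind(base, st, mol, extra, data.frame(flagged = flagged))
}

#' Dispersion-vs-mean regressions of a sweep
#'
#' Linear fits of latency scatter on median latency, half-width SD on
#' mean half-width, and amplitude SD on mean amplitude magnitude, each
#' with a free intercept and with the intercept fixed at 0 (the pooled
#' convention), plus the Spearman correlation.
#'
#' @param table a `sweep_table` or any data.frame with the ensemble-stat
#'   columns.
#' @return named list (`latency`, `half_width`, `amplitude`) of lists
#'   with `slope`, `intercept`, `slope0` (origin-constrained),
#'   `x_intercept`, `rho`, `p_value`, `n`.
#' @export
dispersion_regressions <- function(table) {
  tab <- usable_rows(table)
  if (nrow(tab) < 6L) stop("need at least 6 usable sweep rows")
  reg <- function(x, y) {
    keep <- is.finite(x) & is.finite(y)
    x <- x[keep]; y <- y[keep]
    if (length(unique(x)) < 3L) stop("fewer than 3 distinct x values")
    f <- lm(y ~ x)
    s <- spearman(x, y)
    list(slope = unname(coef(f)[2]), intercept = unname(coef(f)[1]),
         slope0 = sum(x * y) / sum(x * x),
         x_intercept = -unname(coef(f)[1] / coef(f)[2]),
         rho = s$rho, p_value = s$p_value, n = length(x))
  }
  list(latency = reg(tab$median_latency, tab$latency_scatter),
       half_width = reg(tab$mean_half_width, tab$half_width_sd),
       amplitude = reg(abs(tab$mean_amplitude), tab$amplitude_sd))
}

usable_rows <- function(table) {
  tab <- as.data.frame(table)
  if ("flagged" %in% names(tab)) tab <- tab[!tab$flagged, , drop = FALSE]
  tab
}

#' Cross-parameter correlation table
#'
#' The standard summary of how QB statistics co-vary across cascade
#' settings: Spearman correlations over the pooled sweep rows for the
#' eight dispersion-related pairs and six parameter pairs. Amplitude
#' enters as a magnitude, so "faster cascades give larger bumps" shows
#' as a negative latency-amplitude correlation.
#'
#' @param table a `sweep_table` (>= 20 usable rows pooled across
#'   families).
#' @return data.frame with `parameter1`, `parameter2`, `rho`, `p_value`,
#'   `n`.
#' @export
correlation_table <- function(table) {
  tab <- usable_rows(table)
  if (nrow(tab) < 20L)
    warning("fewer than 20 pooled rows: correlation table is unstable")
  v <- list(
    latency = tab$median_latency,
    `latency scatter` = tab$latency_scatter,
    `latency sd` = tab$latency_sd,
    `latency cv` = tab$latency_sd / tab$mean_latency,
    amplitude = abs(tab$mean_amplitude),
    `amplitude sd` = tab$amplitude_sd,
    `amplitude cv` = tab$amplitude_cv,
    `half-width` = tab$mean_half_width,
    `half-width sd` = tab$half_width_sd,
    `half-width cv` = tab$half_width_cv,
    `rise slope` = tab$mean_rise_slope)
  pairs <- rbind(
    c("amplitude", "amplitude sd"),
    c("half-width", "half-width sd"),
    c("latency", "latency scatter"),
    c("latency", "amplitude sd"),
    c("latency", "half-width sd"),
    c("latency", "latency cv"),
    c("latency", "amplitude cv"),
    c("latency", "half-width cv"),
    c("latency", "amplitude"),
    c("latency", "half-width"),
    c("amplitude", "half-width"),
    c("latency", "rise slope"),
    c("rise slope", "half-width"),
    c("rise slope", "amplitude"))
  rows <- apply(pairs, 1L, function(pr) {
    s <- tryCatch(spearman(v[[pr[1]]], v[[pr[2]]]),
                  error = function(e) list(rho = NA_real_,
                                           p_value = NA_real_,
                                           n = sum(stats::complete.cases(
                                             v[[pr[1]]], v[[pr[2]]]))))
    data.frame(parameter1 = pr[1], parameter2 = pr[2], rho = s$rho,
               p_value = s$p_value, n = s$n)
  })
  do.call(rbind, rows)
}
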