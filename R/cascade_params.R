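#' Cascade parameter set for the single-microvillus simulator
#'
#' Bundles the five activation parameters of the phototransduction cascade
#' (the quantities varied in the parametric analysis), the channel
#' complement, the calibration constant converting open channels to
#' current, the PKC activity multiplier on termination kinetics, the
#' lateral-mobility constants and the numerical controls.
#'
#' The control construction [make_control_params()] returns the printed
#' control values: GDP-to-GTP exchange 333 s^-1, Gq and PLC availability
#' 100%, PIP2 breakdown 1428 s^-1, channel sensitivity 0.34, 25 channels
#' per microvillus.
#'
#' @param gdp_gtp_exchange_rate GDP-to-GTP exchange rate by Galpha, s^-1
#'   (control 333, swept 125-1000).
#' @param gq_fraction Gq availability as percent of control (control 100,
#'   swept 10-300). Zero is permitted and yields a flat trace.
#' @param plc_fraction PLC concentration as percent of control (control
#'   100, swept 10-300).
#' @param pip2_breakdown_rate PIP2 hydrolysis rate by active Galpha-PLC,
#'   s^-1 (control 1428, swept 500-10000).
#' @param channel_sensitivity TRP channel sensitivity to DAG,
#'   dimensionless in (0, 1] (control 0.34, swept 0.15-0.8).
#' @param n_channels TRP channels per microvillus (25).
#' @param single_channel_current current per open channel, pA (negative
#'   inward; a calibration constant).
#' @param pkc_activity_factor multiplier on the Ca2+/PKC-dependent
#'   termination rates; 1 is control, 100 reproduces light-adapted
#'   termination kinetics.
#' @param diffusion_params named list of lateral-mobility (encounter-rate)
#'   constants, held at defaults: `k_bind` (Galpha-PLC encounter rate at
#'   control PLC density, s^-1).
#' @param dt simulation step, ms.
#' @param duration total simulated time, ms; must cover the full bump
#'   decay (>= 500 ms for slow parameter sets).
#' @param kinetics named list of the remaining (non-printed) kinetic
#'   constants; defaults were calibrated once so that the control ensemble
#'   matches the printed anchors (mean amplitude about -70.8 pA, median
#'   latency about 30 ms, latency scatter about 6.6 ms). See
#'   [default_kinetics()].
#' @return an object of class `cascade_params` (a named list).
#' @export
cascade_params <- function(gdp_gtp_exchange_rate = 333,
                           gq_fraction = 100,
                           plc_fraction = 100,
                           pip2_breakdown_rate = 1428,
                           channel_sensitivity = 0.34,
                           n_channels = 25L,
                           single_channel_current = -5.85,
                           pkc_activity_factor = 1,
                           diffusion_params = list(k_bind = 1000),
                           dt = 0.1,
                           duration = 500,
                           kinetics = default_kinetics()) {
  p <- list(gdp_gtp_exchange_rate = gdp_gtp_exchange_rate,
            gq_fraction = gq_fraction,
            plc_fraction = plc_fraction,
            pip2_breakdown_rate = pip2_breakdown_rate,
            channel_sensitivity = channel_sensitivity,
            n_channels = as.integer(n_channels),
            single_channel_current = single_channel_current,
            pkc_activity_factor = pkc_activity_factor,
            diffusion_params = modifyList(list(k_bind = 1000), diffusion_params),
            dt = dt,
            duration = duration,
            kinetics = modifyList(default_kinetics(), kinetics))
  class(p) <- "cascade_params"
  validate_cascade_params(p)
  p
}

#' Control parameter set
#'
#' Returns the control cascade parameters; every sweep range brackets its
#' control value (see [default_sweep_grid()]).
#'
#' @param ... overrides passed to [cascade_params()].
#' @return a `cascade_params` object with the printed control values.
#' @export
make_control_params <- function(...) cascade_params(...)

#' Default calibrated kinetic constants
#'
#' The remaining rate constants of the reaction network, not part of the
#' five activation parameters. They follow the structure of the published
#' Drosophila microvillus model and were calibrated once against the
#' printed control anchors (amplitude, median latency, latency scatter);
#' they are not meant to be varied in routine use.
#'
#' @return named list of constants (rates s^-1 unless noted).
#' @export
default_kinetics <- function() {
  list(
    g_pool0 = 50,       # control G-protein pool per microvillus
    plc_pool0 = 70,     # control PLC pool per microvillus
    pip2_total = 3000L, # PIP2 substrate pool
    k_ga_loss = 2,      # spontaneous Galpha deactivation
    k_m = 3,            # basal M* deactivation (Ca/PKC accelerate it)
    k_gap = 22,         # Galpha-PLC turnoff (GAP)
    k_ddeg = 10,        # basal DAG kinase rate
    k_open = 4000,      # TRP max opening rate
    k_close = 30,       # TRP closing rate (base)
    dag_k = 90,         # DAG count at half channel drive (before sensitivity)
    hill = 8,           # gating cooperativity (steep DAG threshold)
    ca_in = 0.05,       # Ca influx per open channel per ms (a.u.)
    tau_ca = 40,        # Ca clearance time constant, ms
    ca_open = 8,        # positive Ca feedback on opening
    ca_close = 4,       # negative Ca feedback (channel inactivation)
    ca_gap = 10,        # Ca acceleration of complex turnoff
    ca_m = 40,          # Ca acceleration of M* shutoff
    ca_half = 3,        # half-saturation of the Ca feedback signal (a.u.)
    ca_ddeg = 30,       # Ca acceleration of DAG removal
    pkc_w = 0.10        # PKC share of turnover at control activity
  )
}

validate_cascade_params <- function(p) {
  stopifnot(inherits(p, "cascade_params"))
  pos <- c("gdp_gtp_exchange_rate", "pip2_breakdown_rate", "dt", "duration")
  for (f in pos)
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]]) ||
        p[[f]] <= 0)
      stop("cascade_params: `", f, "` must be a single positive number")
  for (f in c("gq_fraction", "plc_fraction", "pkc_activity_factor"))
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]]) ||
        p[[f]] < 0)
      stop("cascade_params: `", f, "` must be a single non-negative number")
  if (!(p$channel_sensitivity > 0 && p$channel_sensitivity <= 1))
    stop("cascade_params: channel_sensitivity must be in (0, 1]")
  if (p$n_channels < 1L) stop("cascade_params: n_channels must be >= 1")
  if (!(p$single_channel_current < 0))
    stop("cascade_params: single_channel_current must be negative (inward)")
  invisible(p)
}

#' @export
print.cascade_params <- function(x, ...) {
  cat("<cascade_params>\n")
  cat(sprintf("  GDP->GTP exchange: %g s^-1 | Gq: %g%% | PLC: %g%%\n",
              x$gdp_gtp_exchange_rate, x$gq_fraction, x$plc_fraction))
  cat(sprintf("  PIP2 breakdown: %g s^-1 | channel sensitivity: %g | channels: %d\n",
              x$pip2_breakdown_rate, x$channel_sensitivity, x$n_channels))
  cat(sprintf("  i_single: %g pA | PKC factor: %g | dt: %g ms | duration: %g ms\n",
              x$single_channel_current, x$pkc_activity_factor, x$dt, x$duration))
  invisible(x)
}

#' Read/write cascade parameters as a flat JSON config
#'
#' Keys are exactly the `cascade_params` field names; nested
#' `diffusion_params` and `kinetics` lists are stored as JSON objects.
#'
#' @param params a `cascade_params` object.
#' @param path file path to a JSON document.
#' @return `read_params()` returns a `cascade_params`; `write_params()`
#'   returns `path` invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "cascade_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(cascade_params))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown cascade parameter key(s): ", paste(bad, collapse = ", "))
  do.call(cascade_params, raw)
}
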