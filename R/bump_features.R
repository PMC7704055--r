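#' Per-bump feature extraction
#'
#' Measures the standard quantum-bump descriptors from a single-bump
#' trace: peak amplitude, 10% latency (t1), half-width (t2), 20-80% rise
#' time (t3), 80-20% decay time (t4) and the normalized 20-80% rise slope.
#' All threshold crossings are located by linear interpolation between
#' samples; thresholds are relative to the peak, so features are invariant
#' to vertical scaling.
#'
#' Latency is the first time the response reaches 10% of its maximum.
#' With multiple 50% crossings on one side of the peak the outermost
#' crossings around the global peak are used; if the profile dips below
#' 50% between them a warning of class `microbump_ambiguous_halfwidth` is
#' issued.
#'
#' @param x a trace: a `bump_trace`, a data.frame with `time_ms` and
#'   `current_pA` (or `value`) columns, or a numeric vector (then supply
#'   `time`).
#' @param time time vector in ms when `x` is a plain numeric vector.
#' @param baseline baseline level subtracted before measuring (default 0).
#' @return a one-row data.frame of class `bump_features` with columns
#'   `amplitude`, `latency10`, `t_peak`, `half_width`, `rise_20_80`,
#'   `decay_80_20`, `rise_slope`.
#' @examples
#' wf <- gen_lognormal_qb(10, amplitude = -50)
#' extract_features(sample_waveform(wf, dt = 0.05))
#' @export
extract_features <- function(x, time = NULL, baseline = 0) {
  tr <- as_trace_xy(x, time)
  t <- tr$t; y <- tr$y - baseline
  if (length(t) < 3L) stop("trace too short for feature extraction")
  # work on magnitude; sign taken from the extreme deviation
  pk <- which.max(abs(y))
  s <- sign(y[pk])
  if (s == 0) stop("flat trace: no bump to measure")
  u <- s * y                              # positive-going profile
  A <- u[pk]
  if (pk == 1L || pk == length(u))
    stop("peak at trace edge: bump truncated, extend the simulation window")
  lat10 <- first_crossing(t, u, 0.1 * A)
  if (!is.finite(lat10)) stop("no 10% crossing found before the peak")
  r20 <- rising_crossing(t, u, 0.2 * A, pk)
  r80 <- rising_crossing(t, u, 0.8 * A, pk)
  f80 <- falling_crossing(t, u, 0.8 * A, pk)
  f20 <- falling_crossing(t, u, 0.2 * A, pk)
  hw <- halfwidth_outer(t, u, 0.5 * A, pk)
  rise <- r80 - r20
  out <- data.frame(
    amplitude = s * A,
    latency10 = lat10,
    t_peak = t[pk],
    half_width = hw,
    rise_20_80 = rise,
    decay_80_20 = f20 - f80,
    rise_slope = 0.6 / rise
  )
  class(out) <- c("bump_features", "data.frame")
  out
}

# x -> list(t, y), accepting traces, data frames, waveforms and vectors
as_trace_xy <- function(x, time = NULL) {
  if (inherits(x, "bump_trace"))
    return(list(t = x$time, y = x$current))
  if (inherits(x, "lognormal_waveform")) {
    df <- sample_waveform(x, dt = min(0.05, x$t_peak / 200))
    return(list(t = df$time_ms, y = df$value))
  }
  if (is.data.frame(x)) {
    tc <- intersect(c("time_ms", "time"), names(x))[1]
    yc <- intersect(c("current_pA", "value", "current"), names(x))[1]
    if (is.na(tc) || is.na(yc))
      stop("data frame trace needs time_ms and current_pA/value columns")
    return(list(t = x[[tc]], y = x[[yc]]))
  }
  if (is.numeric(x)) {
    if (is.null(time)) stop("supply `time` alongside a numeric trace")
    return(list(t = time, y = x))
  }
  stop("unsupported trace type: ", paste(class(x), collapse = "/"))
}

# first upward crossing of `level` anywhere before (and including) the peak
first_crossing <- function(t, u, level) {
  idx <- which(u[-1] >= level & u[-length(u)] < level)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  interp_cross(t[i], t[i + 1], u[i], u[i + 1], level)
}

# last upward crossing at or before the peak (adjacent to the peak lobe)
rising_crossing <- function(t, u, level, pk) {
  idx <- which(u[-1] >= level & u[-length(u)] < level)
  idx <- idx[idx < pk]
  if (!length(idx)) return(NA_real_)
  i <- idx[length(idx)]
  interp_cross(t[i], t[i + 1], u[i], u[i + 1], level)
}

# first downward crossing at or after the peak
falling_crossing <- function(t, u, level, pk) {
  idx <- which(u[-length(u)] >= level & u[-1] < level)
  idx <- idx[idx >= pk]
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  interp_cross(t[i], t[i + 1], u[i], u[i + 1], level)
}

halfwidth_outer <- function(t, u, level, pk) {
  up <- which(u[-1] >= level & u[-length(u)] < level)
  dn <- which(u[-length(u)] >= level & u[-1] < level)
  up <- up[up < pk]; dn <- dn[dn >= pk]
  if (!length(up) || !length(dn)) return(NA_real_)
  i <- up[1]; j <- dn[length(dn)]       # outermost crossings around the peak
  t1 <- interp_cross(t[i], t[i + 1], u[i], u[i + 1], level)
  t2 <- interp_cross(t[j], t[j + 1], u[j], u[j + 1], level)
  if (length(up) > 1L || length(dn) > 1L)
    warning(warningCondition(
      "multiple 50% crossings: using outermost crossings around the global peak",
      class = "microbump_ambiguous_halfwidth"))
  t2 - t1
}

interp_cross <- function(t0, t1, y0, y1, level) {
  if (y1 == y0) return(t0)
  t0 + (level - y0) / (y1 - y0) * (t1 - t0)
}
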