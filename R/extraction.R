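#' Calibrate the impulse-response inversion regressions
#'
#' Fits the five relations used to recover quantum-bump statistics from
#' a macroscopic impulse response:
#' \describe{
#'   \item{r1}{composite 10% latency -> median (and mean) QB latency,
#'     proportional through the origin (a composite with no latency
#'     dispersion starts where the aligned average QB starts);}
#'   \item{r2}{median latency -> latency scatter and mean latency ->
#'     latency SD, through the origin (the pooled proportionality);}
#'   \item{r3}{the composite half-width relation
#'     ([composite_halfwidth_relation()]), mapping (impulse half-width,
#'     latency SD) to mean QB half-width;}
#'   \item{r4}{mean half-width -> half-width SD, through the origin;}
#'   \item{r5}{median latency -> amplitude CV, a free linear fit of the
#'     model association.}
#' }
#'
#' @param calib a calibration table: a [run_sweep()] result or any
#'   data.frame with columns `comp_latency10`, `comp_half_width`,
#'   `median_latency`, `mean_latency`, `latency_scatter`, `latency_sd`,
#'   `mean_half_width`, `half_width_sd`, `amplitude_cv` (see
#'   [synthetic_calibration_table()] for a cascade-free source).
#' @param relation optional precomputed [composite_halfwidth_relation()];
#'   when `NULL`, one is built with its half-width CV matched to the
#'   calibration table's pooled half-width dispersion, so that stage 3
#'   accounts for the broadening of impulse responses by QB half-width
#'   variability.
#' @param min_settings minimum usable rows (20).
#' @return an object of class `calibration_regressions`.
#' @export
calibrate <- function(calib, relation = NULL, min_settings = 20L) {
  tab <- usable_rows(calib)
  need <- c("comp_latency10", "comp_half_width", "median_latency",
            "mean_latency", "latency_scatter", "latency_sd",
            "mean_half_width", "half_width_sd", "amplitude_cv")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("calibration table lacks column(s): ",
                         paste(miss, collapse = ", "))
  tab <- tab[stats::complete.cases(tab[need]), , drop = FALSE]
  if (nrow(tab) < min_settings)
    stop("need >= ", min_settings, " usable calibration settings, have ",
         nrow(tab))
  if (max(tab$median_latency) / min(tab$median_latency) < 2)
    stop("latency range below 2x: calibration refused (add faster or ",
         "slower settings)")
  through0 <- function(x, y) sum(x * y) / sum(x * x)
  free_fit <- function(x, y) unname(coef(lm(y ~ x)))
  r1 <- list(slope_median = through0(tab$comp_latency10, tab$median_latency),
             slope_mean = through0(tab$comp_latency10, tab$mean_latency),
             free_median = free_fit(tab$comp_latency10, tab$median_latency))
  r2 <- list(slope_scatter = through0(tab$median_latency, tab$latency_scatter),
             slope_sd = through0(tab$mean_latency, tab$latency_sd))
  hw_cv0 <- stats::median(tab$half_width_sd / tab$mean_half_width)
  r3 <- relation %||% composite_halfwidth_relation(halfwidth_cv = hw_cv0)
  r4 <- list(slope = through0(tab$mean_half_width, tab$half_width_sd))
  r5 <- list(coef = free_fit(tab$median_latency, tab$amplitude_cv))
  gof <- function(x, y, s) 1 - sum((y - s * x)^2) / sum((y - mean(y))^2)
  diag <- list(
    n = nrow(tab),
    r1_r2 = gof(tab$comp_latency10, tab$median_latency, r1$slope_median),
    r2_r2 = gof(tab$median_latency, tab$latency_scatter, r2$slope_scatter),
    r4_r2 = gof(tab$mean_half_width, tab$half_width_sd, r4$slope))
  if (r1$slope_median <= 0 || r2$slope_scatter <= 0 || r4$slope <= 0)
    stop("calibration produced a non-positive slope: table is degenerate")
  structure(list(r1 = r1, r2 = r2, r3 = r3, r4 = r4, r5 = r5,
                 diagnostics = diag),
            class = "calibration_regressions")
}

#' @export
print.calibration_regressions <- function(x, ...) {
  cat("<calibration_regressions>\n")
  cat(sprintf("  r1: median latency = %.3f x impulse latency10 (R2 %.3f)\n",
              x$r1$slope_median, x$diagnostics$r1_r2))
  cat(sprintf("  r2: scatter = %.3f x median latency (R2 %.3f)\n",
              x$r2$slope_scatter, x$diagnostics$r2_r2))
  cat(sprintf("  r3: degree-%d half-width relation\n", x$r3$degree))
  cat(sprintf("  r4: half-width SD = %.3f x mean half-width (R2 %.3f)\n",
              x$r4$slope, x$diagnostics$r4_r2))
  cat(sprintf("  r5: amplitude CV = %.3f %+.4f x median latency\n",
              x$r5$coef[1], x$r5$coef[2]))
  invisible(x)
}

#' Assemble calibration regressions from explicit coefficients
#'
#' For reproducing published species estimates whose regression
#' coefficients are supplied externally rather than refitted. Slopes are
#' through-the-origin unless noted.
#'
#' @param r1_median,r1_mean impulse latency10 -> median / mean QB latency.
#' @param r2_scatter median latency -> latency scatter.
#' @param r2_sd mean latency -> latency SD.
#' @param r4_slope mean half-width -> half-width SD.
#' @param r5_intercept,r5_slope amplitude CV as a linear map of median
#'   latency.
#' @param relation a [composite_halfwidth_relation()] (stage 3); built
#'   with defaults when `NULL`.
#' @return a `calibration_regressions` object usable by
#'   [extract_from_impulse()].
#' @export
manual_calibration <- function(r1_median, r2_scatter,
                               r1_mean = r1_median,
                               r2_sd = r2_scatter,
                               r4_slope = 0.23,
                               r5_intercept = 0.3, r5_slope = 0,
                               relation = NULL) {
  stopifnot(r1_median > 0, r2_scatter > 0, r1_mean > 0, r2_sd > 0,
            r4_slope > 0)
  structure(list(
    r1 = list(slope_median = r1_median, slope_mean = r1_mean,
              free_median = c(0, r1_median)),
    r2 = list(slope_scatter = r2_scatter, slope_sd = r2_sd),
    r3 = relation %||% composite_halfwidth_relation(),
    r4 = list(slope = r4_slope),
    r5 = list(coef = c(r5_intercept, r5_slope)),
    diagnostics = list(n = NA_integer_, r1_r2 = NA_real_, r2_r2 = NA_real_,
                       r4_r2 = NA_real_)),
    class = "calibration_regressions")
}

#' Cascade-free calibration table from synthetic populations
#'
#' Builds the calibration rows from synthetic QB populations instead of
#' cascade sweeps: a family of [qb_population_spec()]s with scatter
#' proportional to median latency, each turned into a high-count impulse
#' response whose 10% latency and half-width are measured.
#'
#' @param median_latencies family of median latencies, ms.
#' @param latency_cv scatter/median proportionality (0.22).
#' @param halfwidth_ratio mean QB half-width as a multiple of median
#'   latency (about 0.67: 20 ms at a 30 ms median).
#' @param halfwidth_cv half-width CV (0.23).
#' @param amplitude_cv_fun function median -> amplitude CV (the model
#'   association; default a mild increasing linear map).
#' @param n_qbs QBs per impulse response.
#' @param seed integer seed.
#' @return data.frame suitable for [calibrate()].
#' @export
synthetic_calibration_table <- function(median_latencies = seq(10, 60, by = 2.5),
                                        latency_cv = 0.22,
                                        halfwidth_ratio = 2 / 3,
                                        halfwidth_cv = 0.23,
                                        amplitude_cv_fun = function(m) 0.1 + 0.004 * m,
                                        n_qbs = 300L, seed = 1L) {
  rows <- lapply(seq_along(median_latencies), function(i) {
    m <- median_latencies[i]
    sct <- latency_cv * m
    spec <- qb_population_spec(
      median_latency = m, latency_scatter = sct,
      mean_half_width = halfwidth_ratio * m, half_width_cv = halfwidth_cv,
      mean_amplitude = -1, amplitude_cv = amplitude_cv_fun(m))
    ir <- gen_impulse_response(spec, n_qbs = n_qbs, seed = sub_seed(seed, i))
    sigma <- asinh(latency_cv)
    data.frame(
      parameter = "synthetic", value = m,
      comp_latency10 = ir$spec$latency10,
      comp_half_width = ir$spec$half_width,
      median_latency = m,
      mean_latency = m * exp(sigma^2 / 2),
      latency_scatter = sct,
      latency_sd = m * exp(sigma^2 / 2) * sqrt(exp(sigma^2) - 1),
      mean_half_width = halfwidth_ratio * m,
      half_width_sd = halfwidth_cv * halfwidth_ratio * m,
      amplitude_cv = amplitude_cv_fun(m),
      flagged = FALSE)
  })
  do.call(rbind, rows)
}

#' Extract QB statistics from an impulse response
#'
#' The five-stage inversion: (1) median and mean QB latency from the
#' impulse 10% latency via r1; (2) latency scatter and SD via r2; (3)
#' mean QB half-width from the impulse half-width and the latency SD via
#' the r3 relation; (4) half-width SD via r4; (5) amplitude CV via r5,
#' reported both as the model-based value and the fixed fallback 0.3
#' (the group-average experimental CV).
#'
#' @param ir an [impulse_response_spec()] (or list with `latency10` and
#'   `half_width`, ms).
#' @param calib a [calibrate()] result.
#' @return an object of class `extracted_qb_stats`: one-row data.frame
#'   with `median_latency`, `mean_latency`, `latency_scatter`,
#'   `latency_sd`, `mean_half_width`, `half_width_sd`, `amplitude_cv`,
#'   `amplitude_cv_fallback`, `extrapolated`.
#' @export
extract_from_impulse <- function(ir, calib) {
  stopifnot(inherits(calib, "calibration_regressions"))
  l10 <- ir$latency10; b <- ir$half_width
  if (!is.finite(l10) || l10 <= 0 || !is.finite(b) || b <= 0)
    stop("impulse response spec needs positive latency10 and half_width")
  med <- calib$r1$slope_median * l10
  mn <- calib$r1$slope_mean * l10
  if (med <= 0) stop("stage 1 produced a non-positive median latency")
  sct <- calib$r2$slope_scatter * med
  lsd <- calib$r2$slope_sd * mn
  if (sct <= 0 || lsd <= 0) stop("stage 2 produced a non-positive dispersion")
  extrap <- FALSE
  x <- withCallingHandlers(
    calib$r3$predict_x(b, lsd),
    warning = function(w) {
      if (grepl("outside the calibrated range", conditionMessage(w))) {
        extrap <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!is.finite(x) || x <= 0)
    stop("stage 3 produced a non-positive mean half-width (b = ", b,
         ", latency SD = ", signif(lsd, 3), ")")
  hw_sd <- calib$r4$slope * x
  if (hw_sd <= 0) stop("stage 4 produced a non-positive half-width SD")
  acv <- calib$r5$coef[1] + calib$r5$coef[2] * med
  out <- data.frame(median_latency = med, mean_latency = mn,
                    latency_scatter = sct, latency_sd = lsd,
                    mean_half_width = x, half_width_sd = hw_sd,
                    amplitude_cv = max(acv, 0),
                    amplitude_cv_fallback = 0.3,
                    extrapolated = extrap)
  class(out) <- c("extracted_qb_stats", "data.frame")
  out
}

#' Closed-loop validation of the extraction algorithm
#'
#' Synthesizes an impulse response from a known QB population, runs the
#' five-stage extraction, and reports per-statistic relative errors.
#' Deterministic given the seed.
#'
#' @param true_spec a [qb_population_spec()] holding the ground truth.
#' @param calib a [calibrate()] result.
#' @param n_qbs QBs in the synthesized impulse response.
#' @param seed integer seed.
#' @param n_replicates impulse responses to average the extracted
#'   statistics over (averaging suppresses the Monte-Carlo noise of a
#'   single response, leaving the algorithm's own error).
#' @return list with `extracted`, `truth` and `rel_errors` (named vector
#'   over the five statistics).
#' @export
roundtrip_validate <- function(true_spec, calib, n_qbs = 100L, seed = 1L,
                               n_replicates = 1L) {
  stopifnot(inherits(true_spec, "qb_population_spec"), n_replicates >= 1L)
  exs <- lapply(seq_len(n_replicates), function(r) {
    ir <- gen_impulse_response(true_spec, n_qbs = n_qbs,
                               seed = sub_seed(seed, r))
    extract_from_impulse(ir$spec, calib)
  })
  ex <- exs[[1L]]
  num <- vapply(ex, is.numeric, logical(1))
  for (cn in names(ex)[num])
    ex[[cn]] <- mean(vapply(exs, function(e) e[[cn]], numeric(1)))
  sigma <- asinh(true_spec$latency_scatter / true_spec$median_latency)
  truth <- c(median_latency = true_spec$median_latency,
             latency_scatter = true_spec$latency_scatter,
             mean_half_width = true_spec$mean_half_width,
             half_width_sd = true_spec$half_width_cv * true_spec$mean_half_width,
             amplitude_cv = true_spec$amplitude_cv)
  est <- c(median_latency = ex$median_latency,
           latency_scatter = ex$latency_scatter,
           mean_half_width = ex$mean_half_width,
           half_width_sd = ex$half_width_sd,
           amplitude_cv = ex$amplitude_cv)
  list(extracted = ex, truth = truth,
       rel_errors = (est - truth) / truth)
}
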