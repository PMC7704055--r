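#' Area-based signal-to-noise ratio of a composite set
#'
#' The signal is the area under the average composite response; the
#' noise is the area under the pointwise SD trace across members. The
#' per-member rectified noise areas (area of |member - average|) are also
#' returned with normal and lognormal fit diagnostics, mirroring the
#' check that the noise-area distribution is normal-like.
#'
#' @param composites a [build_composite()] result.
#' @param min_members members below which a warning is raised (50; SNR
#'   estimates use about 100-120 members).
#' @return an object of class `snr_result`: list with `signal_area`,
#'   `noise_area`, `snr` (NA with `infinite = TRUE` when the noise area
#'   is zero), `member_noise_areas`, and `fits` (normal / lognormal
#'   log-likelihoods and preferred model).
#' @export
snr_area <- function(composites, min_members = 50L) {
  stopifnot(inherits(composites, "composite_set"))
  n_m <- ncol(composites$members)
  if (n_m < 2L) stop("SD trace undefined for a single member")
  if (n_m < min_members)
    warning(warningCondition(
      sprintf("only %d members: SNR estimate is noisy", n_m),
      class = "microbump_small_sample"))
  t <- composites$time
  signal_area <- trapz_area(t, abs(composites$average))
  noise_area <- trapz_area(t, composites$sd_trace)
  member_areas <- apply(abs(composites$members - composites$average), 2L,
                        function(y) trapz_area(t, y))
  fits <- NULL
  if (all(member_areas > 0) && sd(member_areas) > 0) {
    ll_norm <- sum(dnorm(member_areas, mean(member_areas), sd(member_areas),
                         log = TRUE))
    lx <- log(member_areas)
    ll_lnorm <- sum(dlnorm(member_areas, mean(lx), sd(lx), log = TRUE))
    fits <- list(loglik_normal = ll_norm, loglik_lognormal = ll_lnorm,
                 preferred = if (ll_norm >= ll_lnorm) "normal" else "lognormal")
  }
  infinite <- noise_area == 0
  structure(list(signal_area = signal_area, noise_area = noise_area,
                 snr = if (infinite) NA_real_ else signal_area / noise_area,
                 infinite = infinite,
                 member_noise_areas = member_areas, fits = fits),
            class = "snr_result")
}

#' @export
print.snr_result <- function(x, ...) {
  if (x$infinite) cat("<snr_result> noise area 0: SNR infinite\n")
  else cat(sprintf("<snr_result> SNR = %.3g (signal %.4g, noise %.4g)\n",
                   x$snr, x$signal_area, x$noise_area))
  invisible(x)
}

#' Decompose transduction noise by variability source
#'
#' Builds composite responses from a common average QB with selected
#' variability sources switched on — latency (lognormal shifts),
#' half-width (time-axis dilation by normal factors, amplitude
#' preserved), amplitude (vertical scaling by truncated normal factors)
#' — optionally adding photon noise (Poisson QB counts), and measures
#' the area SNR at each summation level.
#'
#' With every source off and photon noise off all members are identical
#' and the SNR is flagged infinite. Adding any variability can only
#' lower the SNR; raising the summation level raises it.
#'
#' @param average_qb the common QB: a [lognormal_waveform()] or a trace
#'   to which one is fitted.
#' @param dispersions list with `median_latency`, `latency_scatter` (or
#'   `latency_sd`), `half_width_cv`, `amplitude_cv`; an
#'   [ensemble_stats()] row is accepted.
#' @param flags character subset of `c("latency", "halfwidth",
#'   "amplitude")` naming the active sources.
#' @param levels summation levels (QBs per composite), default
#'   `c(5, 30, 100)`.
#' @param photon add Poisson variability in the QB count.
#' @param n_members composites per SNR estimate.
#' @param seed integer seed.
#' @param dt grid step, ms.
#' @param recip_a reciprocal-law constant (Hz ms) used to convert each
#'   level's composite half-width into a corner frequency.
#' @return data.frame of class `noise_decomposition`: one row per level
#'   with `level`, `snr`, `infinite`, `signal_area`, `noise_area`,
#'   `composite_half_width`, `f3dB` and the flag columns.
#' @export
decompose_noise <- function(average_qb, dispersions,
                            flags = c("latency", "halfwidth", "amplitude"),
                            levels = c(5, 30, 100), photon = FALSE,
                            n_members = 100L, seed = 1L, dt = 0.5,
                            recip_a = 730) {
  qb <- if (inherits(average_qb, "lognormal_waveform")) average_qb
        else fit_lognormal_waveform(average_qb)
  d <- as.list(dispersions)
  lat_scatter <- d$latency_scatter %||% d$latency_sd
  stopifnot(!is.null(d$median_latency), !is.null(lat_scatter))
  hw_cv <- d$half_width_cv %||% 0.23
  am_cv <- d$amplitude_cv %||% 0.3
  if (hw_cv < 0 || am_cv < 0) stop("CVs must be non-negative")
  bad <- setdiff(flags, c("latency", "halfwidth", "amplitude"))
  if (length(bad)) stop("unknown variability flag(s): ",
                        paste(bad, collapse = ", "))
  base_h <- waveform_halfwidth(qb)
  tp_ratio <- qb$t_peak / base_h
  lat_sampler <- if ("latency" %in% flags) {
    sg <- asinh(lat_scatter / d$median_latency)
    function(k) rlnorm(k, log(d$median_latency), sg)
  } else function(k) rep(d$median_latency, k)
  qb_src <- function(k) {
    hf <- if ("halfwidth" %in% flags) pmax(rnorm(k, 1, hw_cv), 0.05)
          else rep(1, k)
    af <- if ("amplitude" %in% flags) pmax(rnorm(k, 1, am_cv), 0.05)
          else rep(1, k)
    lapply(seq_len(k), function(i)
      gen_lognormal_qb(base_h * hf[i], amplitude = qb$amplitude * af[i],
                       t_peak = tp_ratio * base_h * hf[i]))
  }
  rows <- lapply(seq_along(levels), function(li) {
    lev <- levels[li]
    n_draw <- if (photon) function(m) rpois(m, lev) else as.integer(lev)
    cs <- build_composite(qb_src, n_draw, lat_sampler, n_members,
                          seed = sub_seed(seed, li), dt = dt,
                          allow_empty = photon)
    res <- suppressWarnings(snr_area(cs))
    chw <- tryCatch(
      suppressWarnings(extract_features(cs$average, time = cs$time))$half_width,
      error = function(e) NA_real_)
    data.frame(level = lev, snr = res$snr, infinite = res$infinite,
               signal_area = res$signal_area, noise_area = res$noise_area,
               composite_half_width = chw, f3dB = recip_a / chw,
               latency = "latency" %in% flags,
               halfwidth = "halfwidth" %in% flags,
               amplitude = "amplitude" %in% flags,
               photon = photon)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("noise_decomposition", "data.frame")
  out
}

#' Shannon-Hartley information capacity
#'
#' \eqn{IC = B \log_2(\mathrm{SNR} + 1)} in bits per second, with `B`
#' the corner frequency in Hz.
#'
#' @param B bandwidth (corner frequency), Hz (>= 0).
#' @param snr dimensionless signal-to-noise ratio (>= 0).
#' @return information capacity, bits/s.
#' @examples
#' info_capacity(200, 3)  # 400
#' @export
info_capacity <- function(B, snr) {
  if (any(B < 0) || any(snr < 0)) stop("B and snr must be non-negative")
  B * log2(snr + 1)
}

#' SNR / bandwidth / information-capacity surface
#'
#' Maps the interaction of mean QB half-width and latency dispersion:
#' for every grid cell a composite-response SNR at the given summation
#' level is measured by Monte Carlo (photon noise off), the corner
#' frequency follows from the composite half-width through the
#' reciprocal bandwidth law, and the information capacity is their
#' Shannon-Hartley combination.
#'
#' @param halfwidth_grid mean QB half-widths, ms (the natural range is
#'   about 4-32 ms).
#' @param latency_sd_grid latency SDs, ms (about 1-12 ms).
#' @param halfwidth_cv half-width CV when the half-width source is
#'   active (0.23).
#' @param amplitude_cv amplitude CV, 0 (off) or 0.3.
#' @param level summation level (100).
#' @param n_members composites per cell.
#' @param seed integer seed.
#' @param recip_a reciprocal-law constant, Hz ms (730, the value
#'   recovered by the flicker analysis; see [fit_reciprocal()]).
#' @param latency_cv scatter-to-median ratio fixing the latency
#'   distribution family (0.22).
#' @param median_latency optional fixed median latency, ms; by default
#'   the median co-varies with the dispersion as `latency_sd /
#'   latency_cv`.
#' @param dt grid step, ms.
#' @return data.frame of class `capacity_surface`: one row per cell with
#'   `half_width`, `latency_sd`, `snr`, `f3dB`, `ic`.
#' @export
capacity_surface <- function(halfwidth_grid = seq(4, 32, by = 7),
                             latency_sd_grid = seq(1, 12, length.out = 5),
                             halfwidth_cv = 0.23, amplitude_cv = 0,
                             level = 100L, n_members = 60L, seed = 1L,
                             recip_a = 730, latency_cv = 0.22,
                             median_latency = NULL, dt = 0.5) {
  if (length(halfwidth_grid) < 4L || length(latency_sd_grid) < 4L)
    warning("grid coarser than 4 x 4: surface will be crude")
  flags <- c(if (halfwidth_cv > 0) "halfwidth",
             if (amplitude_cv > 0) "amplitude", "latency")
  rows <- list(); idx <- 0L
  for (h in halfwidth_grid) for (a in latency_sd_grid) {
    idx <- idx + 1L
    qb <- gen_lognormal_qb(h, amplitude = -1)
    med <- if (is.null(median_latency)) a / latency_cv else median_latency
    nd <- decompose_noise(qb,
                          list(median_latency = med, latency_scatter = a,
                               half_width_cv = halfwidth_cv,
                               amplitude_cv = amplitude_cv),
                          flags = flags, levels = level, photon = FALSE,
                          n_members = n_members, seed = sub_seed(seed, idx),
                          dt = dt)
    b <- nd$composite_half_width[1]
    f3 <- recip_a / b
    rows[[idx]] <- data.frame(half_width = h, latency_sd = a, snr = nd$snr[1],
                              composite_half_width = b, f3dB = f3,
                              ic = info_capacity(f3, nd$snr[1]))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("capacity_surface", "data.frame")
  out
}
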