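test_that("averaging identical bumps at random delays returns the bump", {
  wf <- gen_lognormal_qb(10, amplitude = -30)
  base <- sample_waveform(wf, dt = 0.1)
  set.seed(5)
  traces <- lapply(runif(4, 0, 25), function(d)
    data.frame(time_ms = base$time_ms + d, value = base$value))
  avg <- average_bump(traces)
  f <- extract_features(avg)
  expect_equal(f$amplitude, -30, tolerance = 1e-3)
  expect_equal(f$half_width, 10, tolerance = 0.05)
})

test_that("alignment removes latency smearing", {
  wf <- gen_lognormal_qb(10, amplitude = -1)
  set.seed(8)
  lats <- rlnorm(60, log(20), 0.3)
  traces <- lapply(lats, function(d) {
    t <- seq(0, 120, by = 0.1)
    data.frame(time_ms = t, value = eval_waveform(wf, t - d))
  })
  aligned <- extract_features(average_bump(traces))$half_width
  unaligned <- local({
    t <- seq(0, 120, by = 0.1)
    acc <- Reduce(`+`, lapply(lats, function(d) eval_waveform(wf, t - d)))
    suppressWarnings(extract_features(acc / 60, time = t))$half_width
  })
  expect_lt(aligned, unaligned)
  expect_equal(aligned, 10, tolerance = 0.05)
})

test_that("zero dispersion composites are exact multiples with zero SD", {
  wf <- gen_lognormal_qb(8, amplitude = -1)
  cs <- build_composite(wf, n_qbs = 5, lat_sampler(20, 0), n_members = 6,
                        seed = 1, dt = 0.2)
  expect_true(all(cs$sd_trace == 0))
  expect_equal(max(abs(cs$members[, 3] - cs$members[, 1])), 0)
  single <- eval_waveform(wf, cs$time - 20)
  expect_equal(cs$average, 5 * single, tolerance = 1e-12)
  expect_error(build_composite(wf, 0, lat_sampler(20, 0), 3, seed = 1),
               "allow_empty")
})

test_that("lognormal waveform fits are self-consistent and scale in time", {
  wf <- lognormal_waveform(-55, 23, 0.31)
  tr <- sample_waveform(wf, dt = 0.05)
  fit <- fit_lognormal_waveform(tr)
  expect_lt(abs(fit$amplitude - wf$amplitude) / abs(wf$amplitude), 0.005)
  expect_lt(abs(fit$t_peak - wf$t_peak) / wf$t_peak, 0.005)
  expect_lt(abs(fit$shape - wf$shape) / wf$shape, 0.005)
  stretched <- data.frame(time_ms = 2 * tr$time_ms, value = tr$value)
  fit2 <- fit_lognormal_waveform(stretched)
  expect_equal(fit2$t_peak, 2 * fit$t_peak, tolerance = 0.01)
  expect_equal(fit2$shape, fit$shape, tolerance = 0.01)
})

test_that("flicker signals match the Fourier-series oracle for a Gaussian", {
  t <- seq(0, 100, by = 0.05)
  y <- exp(-(t - 50)^2 / (2 * (10 / (2 * sqrt(2 * log(2))))^2))
  fr <- flicker_response(data.frame(time_ms = t, value = y))
  for (i in seq_len(nrow(fr))) {
    oracle <- gauss_flicker_oracle(10, fr$frequency_hz[i])
    expect_lt(abs(fr$signal[i] - oracle) / max(oracle, 0.01), 0.01,
              label = paste("at", fr$frequency_hz[i], "Hz"))
  }
})

test_that("flicker limits and monotonicity behave physically", {
  wf <- gen_lognormal_qb(8, amplitude = -1)
  fr <- flicker_response(wf, frequencies = c(0.5, 5, 12.5, 25, 50, 100, 200))
  expect_equal(fr$signal[1], 1, tolerance = 1e-6)  # isolated pulses
  expect_true(all(diff(fr$signal) <= 1e-9))        # non-increasing
  wide <- flicker_response(gen_lognormal_qb(20), frequencies = 100)
  narrow <- flicker_response(gen_lognormal_qb(6), frequencies = 100)
  expect_gt(narrow$signal, wide$signal)
})

test_that("Hill corner under the amplitude convention hits the 3 dB point", {
  f <- c(5, 12.5, 25, 50, 100, 200)
  fr <- data.frame(frequency_hz = f, signal = 1 / sqrt(1 + (f / 40)^2))
  fit <- fit_hill_corner(fr, ref = "sqrt2")
  expect_equal(fit$f3dB, 40, tolerance = 0.08)
  # vertical scaling leaves the corner untouched
  fr2 <- fr; fr2$signal <- 0.37 * fr2$signal
  expect_equal(fit_hill_corner(fr2, ref = "sqrt2")$f3dB, fit$f3dB,
               tolerance = 1e-6)
  # rising signals are refused
  bad <- fr; bad$signal[5] <- bad$signal[2]
  expect_error(fit_hill_corner(bad), "refusing")
})

test_that("reciprocal law fitting is exact on synthetic data and scales", {
  hw <- c(4, 6, 9, 14, 21, 32, 48)
  fit <- fit_reciprocal(hw, 730 / hw)
  expect_equal(fit$a, 730, tolerance = 1e-9)
  fit2 <- fit_reciprocal(2 * hw, 730 / (2 * hw))
  expect_equal(fit2$a, 730, tolerance = 1e-9)
  expect_error(fit_reciprocal(hw, -730 / hw), "f3dBs")
  expect_warning(fit_reciprocal(c(10, 11, 12, 13, 14), 730 / c(10, 11, 12, 13, 14)),
                 "3x range")
})

test_that("f3dB falls as composite half-width grows, residuals within 15%", {
  hws <- c(5, 8, 12, 18, 26, 38, 50)
  f3 <- vapply(hws, function(h)
    fit_hill_corner(flicker_response(gen_lognormal_qb(h)))$f3dB, numeric(1))
  expect_true(all(diff(f3) < 0))
  fit <- fit_reciprocal(hws, f3)
  expect_lt(max(abs(fit$rel_residuals)), 0.15)
})

test_that("half-width relation: degenerate case, oracle, plateau, inverse", {
  rel <- composite_halfwidth_relation(qb_halfwidths = c(4, 8, 16, 32),
                                      ratios = c(0.5, 1, 2, 4, 8, 16))
  # a = 0 reduces to b = x exactly
  expect_equal(rel$predict_x(17.3, 0), 17.3)
  expect_equal(rel$predict_b(9.4, 0), 9.4)
  # direct convolution oracle at ratio 4 (10 ms QB, 2.5 ms latency SD)
  b_oracle <- microbump:::convolved_halfwidth(10, 2.5)
  expect_lt(abs(rel$predict_b(10, 2.5) - b_oracle) / b_oracle, 0.05)
  # (x + a)/b plateaus once x/a >= 4
  g <- rel$grid
  plateau <- (g$x + g$a) / g$b
  high <- plateau[g$ratio >= 4]
  low <- plateau[g$ratio <= 1]
  expect_lt(diff(range(high)) / mean(high), 0.06)
  expect_lt(mean(low), min(high))       # sum rule underestimates b at low x/a
  # inverse consistency: predict_x(predict_b(x, a), a) = x
  for (x in c(6, 12, 24)) {
    b <- rel$predict_b(x, 3)
    expect_equal(rel$predict_x(b, 3), x, tolerance = 0.02)
  }
  expect_warning(rel$predict_x(200, 2), "outside the calibrated range")
})

test_that("the composite sum rule holds approximately at large x/a", {
  b <- microbump:::convolved_halfwidth(20, 4)   # ratio 5
  expect_equal(b, 20 + 4, tolerance = 0.08)
})

test_that("RC filtering matches the analytic kernel and broadens bumps", {
  wf <- gen_lognormal_qb(15, amplitude = -1)
  tr <- sample_waveform(wf, dt = 0.02, t = seq(0, 400, by = 0.02))
  out <- rc_filter(tr, tau = 20)
  # analytic exponential-kernel convolution oracle (discrete weights
  # a * (1 - a)^j are the exact kernel of the single-pole filter)
  a <- 1 - exp(-0.02 / 20)
  kern <- a * exp(-tr$time_ms / 20)
  oracle <- microbump:::convolve_causal(tr$value, kern)[seq_len(nrow(tr))]
  expect_lt(max(abs(out$value - oracle)), 1e-3 * max(abs(tr$value)))
  # identity at tau = 0 and monotone broadening in tau
  expect_equal(rc_filter(tr, 0)$value, tr$value)
  hw <- vapply(c(0, 5, 20, 50), function(tau)
    suppressWarnings(extract_features(rc_filter(tr, tau)))$half_width,
    numeric(1))
  expect_true(all(diff(hw) > 0))
  expect_equal(hw[1], 15, tolerance = 0.01)
  # filtering preserves relative-threshold feature invariance
  sc <- rc_filter(data.frame(time_ms = tr$time_ms, value = 3 * tr$value), 20)
  expect_equal(suppressWarnings(extract_features(sc))$half_width,
               suppressWarnings(extract_features(out))$half_width,
               tolerance = 1e-9)
})

test_that("latency-dispersed composites never beat the aligned QB response", {
  qb <- gen_lognormal_qb(10, amplitude = -1)
  cs <- build_composite(qb, 400, lat_sampler(25, 5.5), n_members = 1,
                        seed = 4, dt = 0.1)
  comp_fit <- fit_lognormal_waveform(
    data.frame(time_ms = cs$time, value = cs$average))
  fr_qb <- flicker_response(qb)
  fr_comp <- flicker_response(comp_fit)
  expect_true(all(fr_comp$signal <= fr_qb$signal + 1e-6))
})
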