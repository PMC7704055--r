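qb20 <- gen_lognormal_qb(20, amplitude = -1)
ctrl_disp <- list(median_latency = 30, latency_scatter = 6.6,
                  half_width_cv = 0.23, amplitude_cv = 0.3)

test_that("identical members give zero noise and an infinite-SNR flag", {
  cs <- build_composite(qb20, 5, lat_sampler(30, 0), n_members = 60,
                        seed = 2, dt = 0.5)
  res <- snr_area(cs)
  expect_true(res$infinite)
  expect_true(is.na(res$snr))
  expect_equal(res$noise_area, 0)
  cs1 <- build_composite(qb20, 5, lat_sampler(30, 0), n_members = 1, seed = 2)
  expect_error(snr_area(cs1), "single member")
})

test_that("pure Poisson count noise obeys the square-root law", {
  cs <- build_composite(qb20, function(m) rpois(m, 100), lat_sampler(30, 0),
                        n_members = 400, seed = 9, dt = 0.5,
                        allow_empty = TRUE)
  res <- suppressWarnings(snr_area(cs))
  expect_equal(res$snr, 10, tolerance = 0.08)
})

test_that("noise-area distribution of control-like composites is normal-like", {
  src <- function(k) {
    hf <- pmax(rnorm(k, 1, 0.23), 0.05); af <- pmax(rnorm(k, 1, 0.3), 0.05)
    lapply(seq_len(k), function(i)
      gen_lognormal_qb(20 * hf[i], amplitude = -af[i]))
  }
  cs <- build_composite(src, 5, lat_sampler(30, 6.6), n_members = 120,
                        seed = 3, dt = 0.5)
  res <- snr_area(cs)
  expect_identical(res$fits$preferred, "normal")
  expect_length(res$member_noise_areas, 120)
})

test_that("decomposition flags, levels and degenerate cases behave", {
  nd0 <- decompose_noise(qb20, ctrl_disp, flags = character(0),
                         levels = c(5, 30), photon = FALSE, n_members = 20,
                         seed = 1)
  expect_true(all(nd0$infinite))
  expect_error(decompose_noise(qb20, ctrl_disp, flags = "width"), "unknown")
  expect_error(
    decompose_noise(qb20, list(median_latency = 30, latency_scatter = 6.6,
                               half_width_cv = -0.1), seed = 1),
    "non-negative")
})

test_that("SNR grows with summation level and shrinks with added noise", {
  # the control-anchored bump: ~13 ms half-width against a 6.6 ms scatter
  qb13 <- gen_lognormal_qb(13, amplitude = -1)
  nd_all <- decompose_noise(qb13, ctrl_disp, levels = c(5, 30, 100),
                            photon = FALSE, n_members = 100, seed = 5)
  expect_true(all(diff(nd_all$snr) > 0))
  snr_at <- function(flags, seed = 5, photon = FALSE)
    decompose_noise(qb13, ctrl_disp, flags = flags, levels = 100,
                    photon = photon, n_members = 200, seed = seed)$snr
  s_lat <- snr_at("latency")
  s_lat_hw <- snr_at(c("latency", "halfwidth"))
  s_lat_amp <- snr_at(c("latency", "amplitude"))
  s_all <- snr_at(c("latency", "halfwidth", "amplitude"))
  # adding a variability never raises SNR
  expect_lt(s_lat_hw, s_lat)
  expect_lt(s_lat_amp, s_lat)
  expect_lt(s_all, s_lat)
  # ... but by less than ~20% on top of latency at control dispersions
  expect_gt(s_lat_hw / s_lat, 0.8)
  expect_gt(s_lat_amp / s_lat, 0.8)
  # latency alone outweighs half-width and amplitude combined
  s_hw_amp <- snr_at(c("halfwidth", "amplitude"))
  expect_lt(s_lat, s_hw_amp)
})

test_that("transduction noise sources are non-additive", {
  noise_of <- function(flags) {
    nd <- decompose_noise(qb20, ctrl_disp, flags = flags, levels = 100,
                          photon = FALSE, n_members = 100, seed = 8)
    nd$noise_area / nd$signal_area
  }
  n_lat <- noise_of("latency")
  n_hw <- noise_of("halfwidth")
  n_amp <- noise_of("amplitude")
  n_all <- noise_of(c("latency", "halfwidth", "amplitude"))
  expect_lt(n_all, n_lat + n_hw + n_amp)
})

test_that("photon-noise ceiling: transduction variability keeps SNR below sqrt(n)", {
  snr_pois <- function(flags, n_members)
    decompose_noise(qb20, ctrl_disp, flags = flags, levels = 100,
                    photon = TRUE, n_members = n_members, seed = 13)$snr
  s_none <- snr_pois(character(0), 400)
  expect_equal(s_none, 10, tolerance = 0.1)     # sqrt(100) within MC error
  s_full <- snr_pois(c("latency", "halfwidth", "amplitude"), 150)
  expect_lte(s_full, 10)
})

test_that("information capacity is the Shannon-Hartley combination", {
  expect_equal(info_capacity(200, 3), 400)
  expect_equal(info_capacity(0, 7), 0)
  expect_equal(info_capacity(120, 0), 0)
  expect_error(info_capacity(-1, 2), "non-negative")
  expect_error(info_capacity(10, -0.2), "non-negative")
})

test_that("capacity surface reproduces the qualitative landscape", {
  surf <- capacity_surface(halfwidth_grid = c(4, 10, 18, 30),
                           latency_sd_grid = c(1, 3.5, 7, 11),
                           amplitude_cv = 0, level = 100, n_members = 50,
                           seed = 21)
  expect_identical(nrow(surf), 16L)
  expect_equal(surf$ic, info_capacity(surf$f3dB, surf$snr))
  expect_true(all(surf$ic >= 0))
  # duration is an SNR-boosting factor at fixed dispersion
  for (a in unique(surf$latency_sd)) {
    sl <- surf[surf$latency_sd == a, ]
    expect_gt(cor(sl$half_width, sl$snr, method = "spearman"), 0.7)
  }
  # f3dB decreases along both axes; the fast corner sits at the origin
  for (a in unique(surf$latency_sd))
    expect_true(all(diff(surf$f3dB[surf$latency_sd == a]) < 0))
  for (h in unique(surf$half_width))
    expect_true(all(diff(surf$f3dB[surf$half_width == h]) < 0))
  expect_equal(which.max(surf$f3dB),
               which(surf$half_width == 4 & surf$latency_sd == 1))
})

test_that("per unit of CV, amplitude noise is milder than half-width noise", {
  s_amp <- decompose_noise(qb20, ctrl_disp,
                           flags = c("latency", "amplitude"), levels = 100,
                           photon = FALSE, n_members = 150, seed = 17)$snr
  s_hw <- decompose_noise(qb20, ctrl_disp,
                          flags = c("latency", "halfwidth"), levels = 100,
                          photon = FALSE, n_members = 150, seed = 17)$snr
  expect_gt(s_amp, s_hw * 0.97)
})
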