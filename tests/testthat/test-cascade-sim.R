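ctrl <- make_control_params()

test_that("identical (params, seed) pairs reproduce traces bit-for-bit", {
  a <- simulate_bump(ctrl, seed = 42)
  b <- simulate_bump(ctrl, seed = 42)
  expect_identical(a$current, b$current)
  expect_identical(a$n_DAG, b$n_DAG)
  d <- simulate_bump(ctrl, seed = 43)
  expect_false(identical(a$current, d$current))
})

test_that("trace invariants hold for every seed probed", {
  for (s in c(1, 7, 123, 99991)) {
    tr <- simulate_bump(ctrl, seed = s)
    expect_true(all(tr$n_open <= ctrl$n_channels), label = paste("ceiling, seed", s))
    expect_true(all(tr$n_Ga >= 0 & tr$n_GaPLC >= 0 & tr$n_DAG >= 0 &
                      tr$n_open >= 0))
    expect_equal(tr$current, ctrl$single_channel_current * tr$n_open)
    expect_identical(tr$n_open[1], 0L)  # nothing before the photon at t = 0
    expect_identical(tr$n_Ga[1], 0L)
  }
})

test_that("no G protein means no signal at all", {
  tr <- simulate_bump(cascade_params(gq_fraction = 0), seed = 5)
  expect_true(all(tr$current == 0))
  expect_true(all(tr$n_DAG == 0))
})

test_that("degenerate numerics are rejected and truncation is flagged", {
  expect_error(cascade_params(duration = -1), "positive")
  expect_warning(simulate_bump(cascade_params(duration = 40), seed = 101),
                 class = "microbump_truncated_bump")
})

test_that("control ensemble matches the printed anchors", {
  ens <- control_ensemble()
  expect_gte(ens$n_bumps, 130)
  expect_lte(ens$n_bumps, 200)
  fe <- suppressWarnings(ensemble_features(ens))
  st <- suppressWarnings(ensemble_stats(fe))
  # calibration anchors: -70.8 pA, ~30 ms median, ~6.6 ms scatter
  expect_lt(abs(st$mean_amplitude - (-70.8)) / 70.8, 0.15)
  expect_lt(abs(st$median_latency - 30) / 30, 0.15)
  expect_lt(abs(st$latency_scatter - 6.6) / 6.6, 0.20)
  # most runs open fewer than half the 25 channels
  peaks <- vapply(ens$traces[ens$is_bump], function(tr) max(tr$n_open),
                  integer(1))
  expect_gt(mean(peaks < ctrl$n_channels / 2), 0.5)
})

test_that("ensemble mechanics: single trial, thresholds, flat failures", {
  e1 <- run_ensemble(ctrl, n_trials = 1, seed = 3)
  expect_true(e1$bump_probability %in% c(0, 1))
  expect_error(run_ensemble(ctrl, n_trials = 5, threshold = 7, seed = 1),
               "negative")
  # the paper's quality control: averaging no-bump trials gives a flat trace
  e0 <- run_ensemble(cascade_params(gq_fraction = 0), n_trials = 5, seed = 2)
  expect_identical(e0$n_bumps, 0L)
  avg <- ensemble_average(e0, "failures")
  expect_true(all(avg$current_pA == 0))
})

test_that("molecular peaks use the first-maximum rule", {
  tr <- list(time = 0:5, n_Ga = c(0L, 3L, 5L, 5L, 5L, 2L),
             n_GaPLC = c(0L, 1L, 2L, 3L, 2L, 1L),
             n_DAG = c(0L, 2L, 4L, 8L, 6L, 3L))
  mp <- molecular_peaks(tr)
  expect_equal(mp$Nmax_Ga, 5)
  expect_equal(mp$t_Nmax_Ga, 2)        # plateau resolves to its first step
  expect_equal(mp$t_Nmax_DAG, 3)
  tr$n_GaPLC <- rep(0L, 6)
  expect_error(molecular_peaks(tr), "all-zero")
})

test_that("DAG rise slope follows straight-line geometry and scaling", {
  ramp <- list(time = seq(0, 20, by = 0.1),
               n_DAG = as.integer(round(pmin(seq(0, 20, by = 0.1), 10) * 100)))
  expect_equal(dag_rise_slope(ramp), 0.6 / 6, tolerance = 1e-2)
  dilated <- list(time = seq(0, 40, by = 0.2), n_DAG = ramp$n_DAG)
  expect_equal(dag_rise_slope(dilated), 0.5 * dag_rise_slope(ramp),
               tolerance = 1e-6)
  expect_error(dag_rise_slope(list(time = 0:3, n_DAG = c(0L, 0L, 0L, 0L))),
               "below resolution")
})

test_that("within-ensemble correlation pattern matches the cascade logic", {
  ens <- control_ensemble()
  fe <- suppressWarnings(ensemble_features(ens))
  mp <- do.call(rbind, lapply(fe$trial,
                              function(i) molecular_peaks(ens$traces[[i]])))
  mag <- abs(fe$amplitude)
  # amplitudes track how much messenger was made, not when
  s_amp_dag <- spearman(mag, mp$Nmax_DAG)
  expect_gt(s_amp_dag$rho, 0.5)
  expect_lt(s_amp_dag$p_value, 1e-6)
  expect_lt(abs(spearman(mag, mp$t_Nmax_DAG)$rho), 0.4)
  # latencies track the timing of the maxima, not their size, and the
  # correlation strengthens towards the channel-facing stage
  r_ga <- spearman(fe$latency10, mp$t_Nmax_Ga)$rho
  r_plc <- spearman(fe$latency10, mp$t_Nmax_GaPLC)$rho
  r_dag <- spearman(fe$latency10, mp$t_Nmax_DAG)$rho
  expect_gt(r_ga, 0)
  expect_lt(r_ga, r_plc)
  expect_lt(r_plc, r_dag)
  expect_gt(r_dag, 0.7)
  expect_lt(abs(spearman(fe$latency10, mp$Nmax_DAG)$rho), 0.4)
  # size-timing coupling decays along the cascade (strong for Galpha,
  # lost - here slightly inverted - for DAG)
  n_ga <- spearman(mp$Nmax_Ga, mp$t_Nmax_Ga)$rho
  n_plc <- spearman(mp$Nmax_GaPLC, mp$t_Nmax_GaPLC)$rho
  n_dag <- spearman(mp$Nmax_DAG, mp$t_Nmax_DAG)$rho
  expect_gt(n_ga, 0.35)
  expect_true(n_ga > n_plc && n_plc > n_dag)
  expect_lt(abs(n_dag), n_ga)
})

test_that("median latency responds monotonically to cascade speed", {
  med_lat <- function(params, seed) {
    ens <- run_ensemble(params, n_trials = 160, seed = seed)
    fe <- suppressWarnings(ensemble_features(ens))
    expect_gte(nrow(fe), 100)
    median(fe$latency10)
  }
  base <- med_lat(ctrl, 21)
  expect_gt(med_lat(cascade_params(gdp_gtp_exchange_rate = 167), 22), base)
  expect_lt(med_lat(cascade_params(pip2_breakdown_rate = 5000), 23), base)
})

test_that("a hundred-fold PKC activity shortens the bump", {
  hw <- function(pkc, seed) {
    ens <- run_ensemble(cascade_params(pkc_activity_factor = pkc),
                        n_trials = 120, threshold = -2, seed = seed)
    fe <- suppressWarnings(ensemble_features(ens))
    mean(fe$half_width)
  }
  expect_lt(hw(100, 31), hw(1, 31))
})

test_that("traces export with the fixed CSV schema", {
  tr <- simulate_bump(ctrl, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_table(path, schema = "trace")
  expect_equal(back$current_pA, tr$current)
  expect_equal(back$n_open, tr$n_open)
})
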