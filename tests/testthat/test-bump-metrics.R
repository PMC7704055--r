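test_that("triangular-pulse features follow straight-line geometry", {
  tr <- triangle_trace(amp = -50, t_peak = 30, half_base = 10)
  f <- extract_features(tr)
  expect_equal(f$amplitude, -50)
  expect_equal(f$latency10, 21, tolerance = 1e-3)
  expect_equal(f$half_width, 10, tolerance = 1e-3)
  expect_equal(f$rise_20_80, 6, tolerance = 1e-3)
  expect_equal(f$decay_80_20, 6, tolerance = 1e-3)
  expect_equal(f$rise_slope, 0.1, tolerance = 1e-3)
})

test_that("features are invariant to vertical scale and translate in time", {
  tr <- triangle_trace()
  f1 <- extract_features(tr)
  doubled <- tr; doubled$current_pA <- 2 * doubled$current_pA
  f2 <- extract_features(doubled)
  expect_equal(f2$amplitude, 2 * f1$amplitude)
  for (col in c("latency10", "half_width", "rise_20_80", "decay_80_20"))
    expect_equal(f2[[col]], f1[[col]], label = col)
  shifted <- tr; shifted$time_ms <- shifted$time_ms + 15
  f3 <- extract_features(shifted)
  expect_equal(f3$latency10, f1$latency10 + 15, tolerance = 1e-6)
  expect_equal(f3$half_width, f1$half_width, tolerance = 1e-6)
})

test_that("waveform features agree with the dense-grid brute-force oracle", {
  for (hw in c(5, 12, 25)) {
    wf <- gen_lognormal_qb(hw, amplitude = -40)
    f <- extract_features(wf)
    o <- brute_features(wf)
    expect_lt(abs(f$latency10 - o$latency10), 0.1)
    expect_lt(abs(f$half_width - o$half_width), 0.1)
    expect_lt(abs(f$rise_20_80 - o$rise_20_80), 0.1)
  }
})

test_that("edge cases are signalled, not silently mismeasured", {
  t <- seq(0, 10, by = 0.1)
  expect_error(extract_features(-t, time = t), "edge")      # peak at the end
  expect_error(extract_features(rep(0, 50), time = seq(0, 4.9, 0.1)), "flat")
  # twin-lobed profile: ambiguous half-width warning, outermost crossings
  y <- -(dnorm(t, 3, 0.4) + dnorm(t, 7, 0.4))
  expect_warning(extract_features(y, time = t),
                 class = "microbump_ambiguous_halfwidth")
})

test_that("lognormal latency fit recovers generating parameters", {
  x <- gen_latency_samples(30, lognormal_scatter(30, 0.22), n = 5000,
                           seed = 91)
  fit <- fit_latency_lognormal(x)
  expect_equal(fit$mu, 30, tolerance = 0.02)
  expect_equal(fit$sigma, 0.22, tolerance = 0.05)
  expect_equal(fit$scatter, 30 * sinh(0.22), tolerance = 0.05)
  # scatter and plain SD agree within 10% at sigma ~ 0.22
  expect_lt(abs(fit$scatter - fit$sample_sd) / fit$sample_sd, 0.10)
  # density-fit route agrees with the log-moment route on sigma within 5%
  fit2 <- fit_latency_lognormal(x, method = "density")
  expect_lt(abs(fit2$sigma - fit$sigma) / fit$sigma, 0.05)
})

test_that("degenerate and invalid latency inputs behave as specified", {
  same <- rep(25, 40)
  fit <- fit_latency_lognormal(same)
  expect_equal(fit$sigma, 0)
  expect_equal(fit$scatter, 0)
  expect_equal(fit$sample_sd, 0)
  expect_error(fit_latency_lognormal(c(3, -1, 5)), "positive")
  expect_warning(fit_latency_lognormal(rexp(10) + 1),
                 class = "microbump_small_sample")
})

test_that("fit bias is small across sigma at n = 1000", {
  for (sg in c(0.1, 0.25, 0.4)) {
    x <- gen_latency_samples(20, 20 * sinh(sg), 1000, seed = 7)
    fit <- fit_latency_lognormal(x)
    expect_lt(abs(fit$mu - 20) / 20, 0.02)
    expect_lt(abs(fit$sigma - sg) / sg, 0.08)
  }
})

test_that("scatter interval holds 2/3 of the probability for any (mu, sigma)", {
  set.seed(4)
  for (i in 1:25) {
    mu <- runif(1, 1, 200); sg <- runif(1, 0.01, 0.9)
    expect_equal(lognormal_coverage(mu, sg), pnorm(1) - pnorm(-1),
                 tolerance = 1e-10)
  }
  # scatter/SD -> 1 as sigma -> 0 (closed form), monotone approach
  ratio <- function(sg) sinh(sg) / (exp(sg^2 / 2) * sqrt(exp(sg^2) - 1))
  sgs <- c(0.5, 0.3, 0.1, 0.01)
  r <- vapply(sgs, ratio, numeric(1))
  expect_true(all(diff(r) > 0))
  expect_equal(ratio(1e-4), 1, tolerance = 1e-6)
})

test_that("ensemble statistics follow the reporting conventions", {
  const <- data.frame(amplitude = rep(-60, 30), latency10 = rep(25, 30),
                      half_width = rep(15, 30), rise_slope = rep(0.1, 30))
  st <- ensemble_stats(const)
  expect_equal(st$amplitude_sd, 0)
  expect_equal(st$half_width_cv, 0)
  expect_equal(st$latency_scatter, 0)
  # permutation symmetry
  fe <- data.frame(amplitude = -runif(40, 30, 90),
                   latency10 = runif(40, 15, 45),
                   half_width = runif(40, 8, 25),
                   rise_slope = runif(40, 0.05, 0.2))
  st1 <- ensemble_stats(fe)
  st2 <- ensemble_stats(fe[sample.int(40), ])
  expect_equal(st1, st2)
  expect_error(ensemble_stats(fe[0, ]), "empty")
})

test_that("spearman matches brute-force ranks and handles signs", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman(x, exp(x))$rho, 1)
  expect_equal(spearman(x, -x^3)$rho, -1)
  s <- spearman(1:5, c(2, 1, 4, 3, 5))
  expect_equal(s$rho, 0.8)              # 1 - 6*4/(5*24)
  expect_identical(s$method, "exact permutation")
  expect_error(spearman(rep(1, 6), 1:6), "constant")
  expect_error(spearman(1:3, 3:1), "at least 5")
})

test_that("exact permutation p agrees with cor.test on a tie-free case", {
  set.seed(12)
  x <- rnorm(8); y <- rnorm(8)
  ours <- spearman(x, y)
  ref <- cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(ours$rho, unname(ref$estimate))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)
})

test_that("latency fits round-trip through JSON", {
  fit <- fit_latency_lognormal(gen_latency_samples(30, 6.6, 100, seed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_latency_fit(fit, path)
  back <- read_latency_fit(path)
  expect_equal(back$mu, fit$mu)
  expect_equal(back$scatter, fit$scatter)
})
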