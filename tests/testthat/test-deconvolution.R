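test_that("one-period Savitzky-Golay filter preserves constants and lines", {
  t <- default_time(300)
  expect_equal(underlying_signal(rep(5, length(t)), 20, 0.2),
               rep(5, length(t)), tolerance = 1e-9)
  line <- 2 + 0.3 * t
  expect_equal(underlying_signal(line, 20, 0.2), line, tolerance = 1e-9)
})

test_that("the filter attenuates the period-P sinusoid below 5%", {
  # brute-force frequency response at 1/P: filter a unit sinusoid
  t <- default_time(1500)
  u <- underlying_signal(sin(2 * pi * t / 20), 20, 0.2)
  i <- seq(500, 7000)
  expect_lt(max(abs(u[i])), 0.05)
  # ramp + modulation: residual periodic amplitude < 0.05 * A
  A <- 3
  raw <- 10 + 0.5 * t + A * sin(2 * pi * t / 20)
  resid <- underlying_signal(raw, 20, 0.2) - (10 + 0.5 * t)
  expect_lt(max(abs(resid[i])), 0.05 * A)
})

test_that("underlying_signal is linear", {
  t <- default_time(200)
  x <- sin(2 * pi * t / 20) + 0.01 * t
  y <- cos(2 * pi * t / 17) + 2
  lhs <- underlying_signal(3 * x - 2 * y, 20, 0.2)
  rhs <- 3 * underlying_signal(x, 20, 0.2) - 2 * underlying_signal(y, 20, 0.2)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("Hilbert envelope recovers constant and drifting amplitudes", {
  t <- default_time(1500)
  i <- mta:::interior_index(length(t), 20, 0.2)
  env <- upper_envelope(2.5 * sin(2 * pi * t / 20), 20, 0.2)
  expect_equal(mean(env[i]), 2.5, tolerance = 0.01)
  expect_lt(max(abs(env[i] - 2.5)) / 2.5, 0.01)
  expect_equal(upper_envelope(rep(0, 1001), 20, 0.2), rep(0, 1001))
  # drifting amplitude: compare against the per-cycle maxima oracle
  amp <- 1 + 0.5 * t / 1500
  env2 <- upper_envelope(amp * sin(2 * pi * t / 20), 20, 0.2)
  expect_lt(max(abs(env2[i] - amp[i]) / amp[i]), 0.02)
  oracle <- cycle_maxima_envelope(amp * sin(2 * pi * t / 20), t, 20)
  mid <- oracle$t_mid > 100 & oracle$t_mid < 1400
  env_at <- approx(t, env2, xout = oracle$t_mid[mid])$y
  expect_lt(max(abs(env_at - oracle$amp[mid]) / oracle$amp[mid]), 0.02)
})

test_that("reversing signal normalizes, masks, and scales", {
  expect_equal(reversing_signal(rep(0, 10), rep(0.2, 10), 20), rep(0, 10))
  expect_warning(rs <- reversing_signal(c(1, 1), c(0.2, 0), 20), "masked")
  expect_true(is.na(rs[2L]) && is.finite(rs[1L]))
  # scale equivariance: doubling the periodic amplitude doubles RS
  p <- runif(50, 0.5, 2); ts <- runif(50, 0.1, 0.3)
  expect_equal(reversing_signal(2 * p, ts, 20), 2 * reversing_signal(p, ts, 20))
})

test_that("linear temperature response gives a constant reversing signal", {
  s <- tg_scenario(detune_total = 0, noise_f = 0, noise_q = 0)
  m <- simulate_measurement(string_model(), s, temperature_program())
  d <- deconvolve(m)
  rs <- d$rs[!d$edge]
  expect_lt(max(abs(rs - 3 * pi)) / (3 * pi), 0.01)  # |c_T| * 2*pi/P = 3*pi
})

test_that("dominant frequency finds the modulation bin", {
  t <- default_time(1500)
  expect_equal(dominant_frequency(sin(2 * pi * t / 20), 0.2), 0.050,
               tolerance = 1e-6)
  expect_equal(dominant_frequency(5 + 0.1 * t + sin(2 * pi * t / 10), 0.2),
               0.100, tolerance = 1e-6)
  expect_error(dominant_frequency(rep(1, 500), 0.2), "flat")
})

test_that("deconvolution reconstructs the raw signal exactly", {
  m <- simulate_bundle(make_scenario("indomethacin_default", seed = 2))
  d <- deconvolve(m)
  expect_equal(d$ufs + d$periodic, d$raw, tolerance = 1e-12)
  # envelope bound: interior envelope below the window max of |periodic|
  i <- which(!d$edge)
  win <- mta:::sg_window(d$P, d$dt)
  idx <- seq(i[1L], i[length(i)], by = 250)
  for (k in idx) {
    w <- max(1, k - win):min(length(d$periodic), k + win)
    expect_lte(d$p_ue[k], max(abs(d$periodic[w])) * 1.05)
  }
})

test_that("deconvolve validates the requested mode", {
  m <- simulate_bundle(make_scenario("indomethacin_default", seed = 1))
  expect_error(deconvolve(m, "nope"), "not present")
})
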