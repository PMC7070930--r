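test_that("reversing-signal maxima are located and ordered", {
  temp <- seq(30, 70, by = 0.02)
  bump <- function(c, h, w = 0.8) h * exp(-(temp - c)^2 / (2 * w^2))
  one <- 9.4 + bump(45, 20)
  mx <- rs_maxima(one, temp)
  expect_equal(nrow(mx), 1L)
  expect_equal(mx$temp_C, 45, tolerance = 0.05)
  two <- 9.4 + bump(45, 20) + bump(50, 12)
  mx2 <- rs_maxima(two, temp)
  expect_equal(nrow(mx2), 2L)
  expect_equal(mx2$temp_C, c(45, 50), tolerance = 0.05)
  # flat signal with sub-threshold noise reports nothing
  flat <- 9.4 + mta:::with_seed(1, rnorm(length(temp), 0, 0.02))
  expect_equal(nrow(rs_maxima(flat, temp)), 0L)
})

test_that("quality transition uses the minimum when one is pronounced", {
  temp <- seq(30, 70, by = 0.05)
  v <- 1500 + 40 * abs(temp - 50)
  qt <- quality_transition(v, temp)
  expect_equal(qt$temp_C, 50, tolerance = 0.1)
  expect_equal(qt$method, "minimum")
})

test_that("a pure rise falls back to the tangent-intersection onset", {
  temp <- seq(30, 70, by = 0.05)
  w <- 1
  q <- 2000 + 600 * plogis((temp - 50) / w)
  qt <- quality_transition(q, temp)
  expect_equal(qt$method, "rise-onset")
  # analytic tangent construction: flat baseline intersects the inflection
  # tangent (slope r/4w through the midpoint) at center - 2w
  expect_equal(qt$temp_C, 50 - 2 * w, tolerance = 0.3)
  expect_lt(abs(qt$temp_C - 50), 2.2 * w)  # within half the 10-90% width
  expect_error(quality_transition(2000 - 5 * temp, temp), "decreases")
})

test_that("UFS onset finds an exact piecewise-linear slope change", {
  temp <- seq(30, 70, by = 0.05)
  ufs <- -30 * (temp - 30) - 40 * pmax(temp - 45, 0)
  res <- ufs_onset_and_detuning(ufs, temp)
  expect_equal(res$onset_C, 45, tolerance = 0.1)
})

test_that("a constructed 300 Hz step is measured within 2%", {
  temp <- seq(30, 70, by = 0.05)
  ufs <- 163e3 - 300 * plogis((temp - 45) / 0.5)
  res <- ufs_onset_and_detuning(ufs, temp)
  expect_equal(res$detuning_Hz, 300, tolerance = 0.02)
})

test_that("a straight line with noise reports no onset", {
  temp <- seq(30, 70, by = 0.05)
  ufs <- -30 * temp + mta:::with_seed(4, rnorm(length(temp), 0, 0.3))
  res <- ufs_onset_and_detuning(ufs, temp)
  expect_true(is.na(res$onset_C) && is.na(res$detuning_Hz))
})

test_that("UFS onset marks the leading edge of the detuning step", {
  r <- cached_default_report(1)
  sw <- 0.5
  expect_lte(r$ufs_onset, 45)
  expect_gte(r$ufs_onset, 45 - 3.5 * sw)
})

test_that("default-scenario report recovers both transition temperatures", {
  r <- cached_default_report(1)
  expect_equal(r$tg_f, 45, tolerance = 0.6 / 45)   # one period's span ~0.53 degC
  expect_equal(r$tg_q, 50, tolerance = 0.5 / 50)   # within step_width
  expect_identical(r$tg_q_method, "minimum")
  expect_gte(r$tg_q, r$tg_f)
  expect_equal(r$delta_qf, r$tg_q - r$tg_f)
  expect_equal(r$detuning, 300, tolerance = 0.05)
  expect_false("no-rs-maximum" %in% r$flags)
})

test_that("report handles an empty maxima list and flags multiples", {
  m <- simulate_bundle(make_scenario("indomethacin_two_step", seed = 3))
  d <- deconvolve(m)
  r <- build_report(d, m$quality[[1L]])
  expect_true("multiple-maxima" %in% r$flags)
  expect_identical(r$tg_f, r$rs_maxima$temp_C[1L])
  # featureless trace: no maxima, flag set, tg_f absent
  s0 <- tg_scenario(detune_total = 0, noise_f = 0.05, noise_q = 1)
  m0 <- simulate_measurement(string_model(), s0, temperature_program())
  r0 <- build_report(deconvolve(m0), m0$quality[[1L]])
  expect_true("no-rs-maximum" %in% r0$flags)
  expect_true(is.na(r0$tg_f))
})

test_that("detected temperatures are equivariant under a temperature shift", {
  m <- simulate_bundle(make_scenario("indomethacin_default", seed = 5))
  d <- deconvolve(m)
  r0 <- build_report(d, m$quality[[1L]])
  shift <- 7
  d2 <- d
  d2$temperature <- d$temperature + shift
  r1 <- build_report(d2, m$quality[[1L]])
  expect_equal(r1$tg_f, r0$tg_f + shift, tolerance = 1e-8)
  expect_equal(r1$tg_q, r0$tg_q + shift, tolerance = 1e-8)
  expect_equal(r1$ufs_onset, r0$ufs_onset + shift, tolerance = 1e-8)
  expect_equal(r1$delta_qf, r0$delta_qf, tolerance = 1e-8)
})
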