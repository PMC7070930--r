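test_that("sampled flexural shapes classify to their harmonic with no errors", {
  for (n in 1:4) {
    lab <- classify_mode(sample_mode_shape(n))
    expect_identical(lab$harmonic, n)
    expect_false(lab$torsional)
    expect_identical(lab$descriptor, "flexural")
  }
})

test_that("classification is invariant to global phase and scaling", {
  base <- classify_mode(sample_mode_shape(3))
  for (phase in c(0.4, 1.2, pi / 2)) {
    g <- sample_mode_shape(3, phase = phase)
    g$amplitude <- g$amplitude * 7.3
    lab <- classify_mode(g)
    expect_identical(lab$harmonic, base$harmonic)
    expect_identical(lab$descriptor, base$descriptor)
  }
})

test_that("torsional admixture marks a mode as mixed", {
  lab <- classify_mode(sample_mode_shape(1, torsion = 0.5))
  expect_identical(lab$harmonic, 1L)
  expect_true(lab$torsional)
  expect_identical(lab$descriptor, "mixed")
  # a single-row grid cannot assess torsion
  g <- sample_mode_shape(2, ny = 1)
  expect_warning(lab1 <- classify_mode(g), "single-row")
  expect_true(is.na(lab1$torsional))
  expect_identical(lab1$harmonic, 2L)
})

test_that("the low-resolution 21-point grid still classifies n = 1..3", {
  for (n in 1:3) {
    expect_identical(classify_mode(sample_mode_shape(n, nx = 7, ny = 3))$harmonic, n)
  }
})

test_that("the prominent mode is the largest magnitude in the band", {
  spec <- data.frame(frequency = seq(150e3, 520e3, by = 500))
  spec$magnitude <- dnorm(spec$frequency, 163e3, 800) +
    2 * dnorm(spec$frequency, 343e3, 800)
  freqs <- c(`1.1` = 163e3, `2` = 343e3, `3` = 489e3)
  expect_identical(prominent_mode(spec, c(150e3, 200e3), freqs), "1.1")
  expect_identical(prominent_mode(spec, c(150e3, 400e3), freqs), "2")
  expect_error(prominent_mode(spec, c(600e3, 700e3), freqs), "no spectral peak")
  expect_error(prominent_mode(spec, c(2, 1), freqs), "band")
})

test_that("mode switches are debounced", {
  expect_length(detect_mode_switches(rep("1.1", 10)), 0L)
  lab <- c(rep("1.1", 6), rep("2", 6))
  expect_identical(detect_mode_switches(lab), 7L)
  # three-sample flicker is ignored at debounce 4
  flick <- c(rep("1.1", 6), rep("2", 3), rep("1.1", 8))
  expect_length(detect_mode_switches(flick, debounce_n = 4), 0L)
  expect_identical(detect_mode_switches(flick, debounce_n = 3), c(7L, 10L))
})

test_that("an injected prominent-mode switch is recovered at its time", {
  b <- make_scenario("mode_switch", seed = 1)
  m <- simulate_bundle(b)
  # prominent-mode label series: mode 1.1 until the switch temperature
  labels <- ifelse(m$temperature < b$switch_temp_C, "1.1", "1.2")
  sw <- detect_mode_switches(labels, debounce_n = 3)
  expect_length(sw, 1L)
  expect_equal(m$temperature[sw], b$switch_temp_C, tolerance = 0.3 / 52)
})

test_that("local responsivity follows the squared mode shape", {
  expect_equal(local_responsivity(0.5, 1), 1)
  expect_equal(local_responsivity(0.5, 2), 0, tolerance = 1e-12)
  expect_equal(local_responsivity(0.25, 1), 0.5)
  x <- runif(25)
  for (n in 1:3) {
    expect_equal(local_responsivity(x, n), local_responsivity(1 - x, n),
                 tolerance = 1e-12)
  }
  expect_error(local_responsivity(1.2), "\\[0, 1\\]")
})

test_that("animation frames sweep the displacement through one cycle", {
  g <- sample_mode_shape(2)
  fr <- mode_animation_frames(g, n_frames = 8)
  expect_identical(dim(fr), c(8L, g$n_points))
  expect_equal(fr[1L, ], Re(g$amplitude))
  # half a cycle later the displacement is inverted
  expect_equal(fr[5L, ], -fr[1L, ], tolerance = 1e-12)
})
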