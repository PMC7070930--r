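one_disk_scenario <- function(diameter, noise_sd = 0, seed = 1) {
  frame_scenario(width = 128, height = 96, px_per_um = 1.5,
                 particles = data.frame(cx = 64, cy = 48, diameter = diameter,
                                        brightness = 200),
                 noise_sd = noise_sd, seed = seed)
}

test_that("a particle-free scenario renders uniform background frames", {
  fs <- frame_scenario(width = 64, height = 32,
                       particles = data.frame(cx = numeric(0), cy = numeric(0),
                                              diameter = numeric(0),
                                              brightness = numeric(0)),
                       noise_sd = 0)
  stack <- render_frames(fs, c(40, 50))
  expect_true(all(stack == fs$background))
})

test_that("a static disk's pixel area matches pi*r^2 within 5%", {
  for (diam in c(10, 16, 24)) {
    fs <- one_disk_scenario(diam)
    stack <- render_frames(fs, 30)       # far below the transition: static
    r <- diam / 2 * 1.5
    thr <- fs$background + 0.5 * (200 - fs$background)
    count <- sum(stack[, , 1L] > thr)    # brute-force count at threshold
    expect_equal(count, pi * r^2, tolerance = 0.05)
  }
})

test_that("particles shrink, pass a minimum, then exceed their initial area", {
  # diameter chosen so the ~2.5% radius shrink crosses pixel-count quanta
  fs <- one_disk_scenario(14)
  temps <- seq(40, 62, length.out = 111)
  stack <- render_frames(fs, temps)
  thr <- fs$background + 0.5 * (200 - fs$background)
  area <- apply(stack > thr, 3, sum)
  k <- which.min(area)
  expect_gt(k, 1L)
  expect_lt(k, length(area))
  expect_lt(min(area), area[1L])
  expect_gt(area[length(area)], area[1L])
  # minimum plateau (pixel counts are quantized) brackets
  # tg_dynamic + lag_per_um * diameter
  plateau <- range(temps[area == min(area)])
  expect_lte(plateau[1L] - 1.2, 50 + 0.2 * 14)
  expect_gte(plateau[2L] + 1.2, 50 + 0.2 * 14)
})

test_that("larger particles reach their area minimum later (heating lag)", {
  temps <- seq(40, 62, length.out = 111)
  kmin <- vapply(c(12, 14, 18, 22), function(diam) {
    fs <- one_disk_scenario(diam)
    stack <- render_frames(fs, temps)
    thr <- fs$background + 0.5 * (200 - fs$background)
    which.min(apply(stack > thr, 3, sum))
  }, numeric(1))
  expect_true(all(diff(kmin) >= 0))
})

test_that("rendering is deterministic and stays within 8-bit range", {
  fs <- one_disk_scenario(8, noise_sd = 2, seed = 9)
  s1 <- render_frames(fs, c(45, 50, 55))
  s2 <- render_frames(fs, c(45, 50, 55))
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0 & s1 <= 255))
})

test_that("particles extending past the frame edge are clipped with a warning", {
  fs <- frame_scenario(width = 64, height = 48,
                       particles = data.frame(cx = 2, cy = 24, diameter = 10,
                                              brightness = 200),
                       noise_sd = 0)
  expect_warning(stack <- render_frames(fs, 45), "clipped")
  expect_identical(dim(stack), c(48L, 64L, 1L))
})
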