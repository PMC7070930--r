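render_disks <- function(diameters, px_per_um = 1.5, width = 256, height = 96) {
  cx <- seq(40, width - 40, length.out = max(length(diameters), 2))[seq_along(diameters)]
  fs <- frame_scenario(width = width, height = height, px_per_um = px_per_um,
                       particles = data.frame(cx = cx, cy = height / 2,
                                              diameter = diameters,
                                              brightness = 200),
                       noise_sd = 0)
  render_frames(fs, 30)[, , 1L]
}

test_that("a blank frame yields empty masks on every level", {
  masks <- contour_levels(matrix(30, 40, 60), px_per_um = 1.5)
  expect_length(masks, 3L)
  expect_true(all(vapply(masks, sum, numeric(1)) == 0))
})

test_that("particles are assigned to size classes by equivalent diameter", {
  f <- render_disks(8)
  areas <- vapply(contour_levels(f, 1.5), sum, numeric(1))
  expect_equal(areas[2L] > 0, TRUE)
  expect_equal(areas[c(1L, 3L)], c(0, 0))
  # 3 um and 12 um disks land in levels 1 and 3 with their full pixel counts
  f2 <- render_disks(c(3, 12))
  masks <- contour_levels(f2, 1.5)
  thr <- mta:::segmentation_threshold(f2)
  lab <- EBImage::bwlabel(matrix(as.integer(f2 > thr), nrow(f2)))
  counts <- sort(tabulate(lab[lab > 0]))
  expect_equal(sum(masks[[1L]]), counts[1L])
  expect_equal(sum(masks[[3L]]), counts[2L])
  expect_equal(sum(masks[[2L]]), 0)
})

test_that("level assignment is invariant to a consistent scale change", {
  f1 <- render_disks(c(4, 8), px_per_um = 1)
  f2 <- render_disks(c(4, 8), px_per_um = 2, width = 512, height = 192)
  a1 <- vapply(contour_levels(f1, 1), function(m) sum(m) > 0, logical(1))
  a2 <- vapply(contour_levels(f2, 2), function(m) sum(m) > 0, logical(1))
  expect_identical(a1, a2)
})

test_that("a static stack tracks exactly constant areas", {
  fs <- frame_scenario(width = 128, height = 64, px_per_um = 1.5,
                       particles = data.frame(cx = c(40, 90), cy = 32,
                                              diameter = c(4, 12),
                                              brightness = 200),
                       noise_sd = 0)
  stack <- render_frames(fs, rep(30, 12) + seq(0, 0.011, 0.001))
  res <- track_levels(stack, 1.5, P = 20, dt = 2)
  for (l in 1:3) expect_length(unique(res$areas[, l]), 1L)
})

test_that("a shrinking-only particle gives a non-increasing smoothed series", {
  fs <- frame_scenario(width = 96, height = 64, px_per_um = 1.5,
                       particles = data.frame(cx = 48, cy = 32, diameter = 10,
                                              brightness = 200),
                       noise_sd = 0, tg_dynamic = 100, lag_per_um = 0)
  stack <- render_frames(fs, seq(60, 96, length.out = 60))  # approach, never pass
  res <- track_levels(stack, 1.5, P = 20, dt = 2)
  s <- res$smoothed[, 2L]
  expect_true(all(diff(s) <= 1e-9))
})

test_that("area minima are found per level and absent for monotone series", {
  fs <- frame_scenario(seed = 2)
  temps <- seq(40, 60, length.out = 121)
  res <- track_levels(render_frames(fs, temps), 1.5, P = 20, dt = 2)
  am <- area_minima(res)
  expect_false(any(is.na(am$temp_C)))
  expect_true(all(diff(am$temp_C) >= 0))   # smaller classes respond sooner
  # constructed minimum at a known frame
  res2 <- res
  res2$smoothed <- cbind(c(5, 4, 3, 2, 5, 6, 7, 8, 9, 10))
  res2$temp_C <- 41:50
  am2 <- area_minima(res2, central = 1)
  expect_identical(am2$frame[1L], 4L)
  res3 <- res2
  res3$smoothed <- cbind(1:10)
  expect_true(is.na(area_minima(res3, central = 1)$frame[1L]))
})

test_that("mismatched or too-short stacks are rejected", {
  expect_error(track_levels(array(0, c(4, 4, 1)), 1.5, 20, 2), "2 frames")
})
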