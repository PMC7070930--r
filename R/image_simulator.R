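#' Synthetic microscope frame scenario
#'
#' Describes a stack of 8-bit grayscale microscope frames of sample
#' particles on a string through the glass transition: each particle first
#' shrinks slightly, then spreads (widens) as it liquefies, with a
#' size-dependent temperature lag (larger particles take longer to heat
#' through).
#'
#' @param width,height frame size, pixels.
#' @param px_per_um image scale, pixels per micrometer.
#' @param particles data frame with columns `cx`, `cy` (center, pixels),
#'   `diameter` (micrometers) and `brightness` (gray level, > background).
#' @param shrink_frac fractional projected-area loss before spreading,
#'   in (0, 1).
#' @param spread_frac fractional projected-area gain after liquefaction,
#'   > 0.
#' @param lag_per_um temperature lag per micrometer of particle diameter,
#'   degrees C.
#' @param tg_dynamic liquefaction temperature, degrees C; a particle of
#'   diameter d reaches its area minimum at `tg_dynamic + lag_per_um * d`.
#' @param transition_width temperature scale of the shrink/spread shape,
#'   degrees C.
#' @param background background gray level, 0-255.
#' @param noise_sd pixel noise standard deviation, gray levels.
#' @param seed integer seed for the pixel noise.
#' @return An object of class `mta_frames_scenario`.
#' @export
frame_scenario <- function(width = 512, height = 128, px_per_um = 1.5,
                           particles = default_particle_table(),
                           shrink_frac = 0.05, spread_frac = 0.6,
                           lag_per_um = 0.2, tg_dynamic = 50,
                           transition_width = 1, background = 30,
                           noise_sd = 2, seed = 1L) {
  if (shrink_frac <= 0 || shrink_frac >= 1) stop("shrink_frac must lie in (0, 1)")
  if (spread_frac <= 0) stop("spread_frac must be positive")
  stopifnot(is.data.frame(particles),
            all(c("cx", "cy", "diameter", "brightness") %in% names(particles)))
  if (any(particles$diameter <= 0)) stop("particle diameters must be positive")
  if (any(particles$brightness <= background)) {
    stop("particle brightness must exceed the background level")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 px_per_um = px_per_um, particles = particles,
                 shrink_frac = shrink_frac, spread_frac = spread_frac,
                 lag_per_um = lag_per_um, tg_dynamic = tg_dynamic,
                 transition_width = transition_width,
                 background = background, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "mta_frames_scenario")
}

# A handful of particles spread along the string midline, sizes spanning
# the three contour levels (2-25 um deposition range). Diameters sit far
# enough inside their size class that the shrink/spread excursion
# (sqrt(1 + spread_frac) ~ 1.27x in diameter) does not cross a class edge.
default_particle_table <- function() {
  data.frame(
    cx = c(80, 160, 235, 310, 390, 455),
    cy = c(60, 70, 58, 66, 62, 68),
    diameter = c(3, 3.5, 6, 7.5, 14, 18),
    brightness = 200
  )
}

# Projected-area factor vs effective temperature tau = T - (tg + lag*d):
# 1 far below, minimum (1 - shrink) exactly at tau = 0, then rising to
# (1 + spread). Continuous at tau = 0.
area_factor <- function(tau, shrink, spread, w) {
  lower <- 1 - shrink * exp(-(tau / (2 * w))^2)
  upper <- (1 - shrink) + (shrink + spread) * 2 * (logistic(tau / w) - 0.5)
  ifelse(tau < 0, lower, upper)
}

#' Render a synthetic frame stack
#'
#' Renders one anti-aliased 8-bit grayscale frame per temperature sample.
#' Each particle is drawn as a disk whose radius follows the
#' shrink-then-spread law as a function of its lag-shifted temperature
#' (radius scales as the square root of the projected-area factor).
#' Particles partially outside the frame are clipped with a warning.
#'
#' @param scenario an [frame_scenario()].
#' @param temperature increasing temperature series, one frame per value.
#' @return An integer array of dimension `c(height, width, n_frames)` with
#'   values in 0-255, with attribute `temp_C` carrying the temperature of
#'   each frame.
#' @examples
#' fs <- frame_scenario(width = 64, height = 48,
#'   particles = data.frame(cx = 32, cy = 24, diameter = 8, brightness = 200))
#' stack <- render_frames(fs, c(45, 50, 55))
#' dim(stack)
#' @export
render_frames <- function(scenario, temperature) {
  stopifnot(inherits(scenario, "mta_frames_scenario"))
  if (length(temperature) < 1L) stop("need at least one temperature sample")
  if (is.unsorted(temperature, strictly = FALSE)) {
    stop("temperature series must be increasing")
  }
  h <- scenario$height; w <- scenario$width
  p <- scenario$particles
  r0 <- p$diameter / 2 * scenario$px_per_um
  if (nrow(p) > 0 &&
      any(p$cx - max(r0) * sqrt(1 + scenario$spread_frac) < 1 |
          p$cx + max(r0) * sqrt(1 + scenario$spread_frac) > w |
          p$cy - max(r0) * sqrt(1 + scenario$spread_frac) < 1 |
          p$cy + max(r0) * sqrt(1 + scenario$spread_frac) > h)) {
    warning("particle(s) extend outside the frame; clipped")
  }
  nfr <- length(temperature)
  stack <- array(0L, dim = c(h, w, nfr))
  with_seed(scenario$seed, {
    for (k in seq_len(nfr)) {
      frame <- matrix(scenario$background, nrow = h, ncol = w)
      for (i in seq_len(nrow(p))) {
        tau <- temperature[k] - scenario$tg_dynamic -
          scenario$lag_per_um * p$diameter[i]
        r <- r0[i] * sqrt(area_factor(tau, scenario$shrink_frac,
                                      scenario$spread_frac,
                                      scenario$transition_width))
        xs <- max(1L, floor(p$cx[i] - r - 1)):min(w, ceiling(p$cx[i] + r + 1))
        ys <- max(1L, floor(p$cy[i] - r - 1)):min(h, ceiling(p$cy[i] + r + 1))
        d <- sqrt(outer((ys - p$cy[i])^2, (xs - p$cx[i])^2, "+"))
        cov <- clamp(r - d + 0.5, 0, 1)   # anti-aliased disk coverage
        patch <- frame[ys, xs, drop = FALSE]
        lit <- scenario$background + (p$brightness[i] - scenario$background) * cov
        frame[ys, xs] <- pmax(patch, lit)
      }
      if (scenario$noise_sd > 0) {
        frame <- frame + stats::rnorm(length(frame), 0, scenario$noise_sd)
      }
      stack[, , k] <- as.integer(round(clamp(frame, 0, 255)))
    }
  })
  attr(stack, "temp_C") <- temperature
  stack
}

#' Write a frame stack as numbered PNG files
#'
#' Writes `frame_%04d.png` files plus an index CSV `frames.csv` with columns
#' `frame,temp_C`.
#'
#' @param stack array from [render_frames()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the index data frame.
#' @export
write_frames <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  temp <- attr(stack, "temp_C")
  n <- dim(stack)[3L]
  for (k in seq_len(n)) {
    png::writePNG(stack[, , k] / 255,
                  file.path(dir, sprintf("frame_%04d.png", k)))
  }
  idx <- data.frame(frame = seq_len(n), temp_C = temp)
  utils::write.csv(idx, file.path(dir, "frames.csv"), row.names = FALSE)
  invisible(idx)
}

#' Read a frame stack written by [write_frames()]
#'
#' @param dir directory containing `frame_*.png` files and `frames.csv`.
#' @return Integer array as produced by [render_frames()].
#' @export
read_frames <- function(dir) {
  idx_path <- file.path(dir, "frames.csv")
  if (!file.exists(idx_path)) {
    stop(sprintf("missing frame index CSV: %s", idx_path))
  }
  idx <- utils::read.csv(idx_path)
  files <- file.path(dir, sprintf("frame_%04d.png", idx$frame))
  first <- png::readPNG(files[1L])
  stack <- array(0L, dim = c(nrow(first), ncol(first), length(files)))
  for (k in seq_along(files)) {
    stack[, , k] <- as.integer(round(png::readPNG(files[k]) * 255))
  }
  attr(stack, "temp_C") <- idx$temp_C
  stack
}
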