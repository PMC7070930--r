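#' Grid-overlay mode-shape measurement
#'
#' Vibrational amplitudes measured on a grid of points overlaid on a string
#' at a single resonance frequency, as recorded by a scanning vibrometer
#' (typically 69 points, 23 along the length by 3 across the width; a
#' low-resolution 21-point variant uses 7 by 3).
#'
#' @param x_frac fractional position along the string length, in \[0, 1\].
#' @param y_frac fractional position across the string width, in \[0, 1\].
#' @param amplitude complex vibrational amplitude per point.
#' @param frequency resonance frequency of the measured mode, Hz.
#' @return An object of class `mta_mode_grid`.
#' @export
mode_grid <- function(x_frac, y_frac, amplitude, frequency) {
  n <- length(x_frac)
  if (length(y_frac) != n || length(amplitude) != n) {
    stop("x_frac, y_frac and amplitude must have equal length")
  }
  if (n < 6L) stop("grid needs at least 6 points")
  if (!all(is.finite(Mod(amplitude)))) stop("amplitudes must be finite")
  structure(list(x_frac = x_frac, y_frac = y_frac,
                 amplitude = as.complex(amplitude),
                 frequency = frequency, n_points = n),
            class = "mta_mode_grid")
}

#' Sample an ideal mode shape onto a grid
#'
#' Builds a [mode_grid()] from the flexural shape `sin(n*pi*x)` at `nx` by
#' `ny` points, optionally with an antisymmetric torsional admixture across
#' the width (`torsion * (y - 1/2) * 2`), as used for testing and for the
#' bundled scenarios.
#'
#' @param n harmonic index.
#' @param nx,ny grid resolution along length and width.
#' @param torsion torsional admixture, 0 for a pure flexural shape.
#' @param frequency resonance frequency to record, Hz.
#' @param phase global complex phase applied to all amplitudes.
#' @return An `mta_mode_grid`.
#' @export
sample_mode_shape <- function(n, nx = 23, ny = 3, torsion = 0,
                              frequency = n * 163e3, phase = 0) {
  g <- expand.grid(x = seq(0, 1, length.out = nx),
                   y = seq(0, 1, length.out = ny))
  amp <- sin(n * pi * g$x) * (1 + torsion * 2 * (g$y - 0.5))
  mode_grid(g$x, g$y, amp * exp(1i * phase), frequency)
}

#' Classify a mode shape
#'
#' Labels a grid-overlay measurement with its harmonic index and whether it
#' is a pure flexural or a mixed (torsionally involved) mode. The complex
#' amplitudes are first rotated to the global phase that maximizes their
#' real energy (the classification is invariant to a global phase and to
#' scaling); the harmonic is one plus the number of sign changes of the
#' width-averaged real amplitude along the length, and the torsional flag is
#' set when the maximum amplitude difference between the outer width rows
#' exceeds `mixedness * max|amplitude|`.
#'
#' @param grid an [mta_mode_grid][mode_grid()] with at least two distinct
#'   width rows (a single-row grid classifies the harmonic but flags the
#'   torsional assessment as indeterminate).
#' @param mixedness threshold on the normalized row difference above which a
#'   mode is labeled mixed.
#' @return List of class `mta_mode_label` with `harmonic`, `torsional`
#'   (logical, `NA` if indeterminate), and `descriptor` (`"flexural"` or
#'   `"mixed"`, `NA` if indeterminate).
#' @examples
#' classify_mode(sample_mode_shape(3))
#' classify_mode(sample_mode_shape(1, torsion = 0.5))
#' @export
classify_mode <- function(grid, mixedness = 0.3) {
  stopifnot(inherits(grid, "mta_mode_grid"))
  a <- grid$amplitude
  # Global phase alignment: rotate so the summed squared amplitude is real.
  phi <- 0.5 * Arg(sum(a^2))
  re <- Re(a * exp(-1i * phi))
  amax <- max(abs(re))
  if (amax == 0) stop("grid has zero amplitude everywhere")
  re <- re / amax

  xs <- sort(unique(grid$x_frac))
  prof <- vapply(xs, function(x) mean(re[grid$x_frac == x]), numeric(1))
  # Count sign changes of the width-averaged profile, ignoring near-node
  # samples (|value| below 5% of the profile maximum).
  keep <- prof[abs(prof) > 0.05 * max(abs(prof))]
  harmonic <- 1L + sum(diff(sign(keep)) != 0)

  ys <- sort(unique(grid$y_frac))
  if (length(ys) < 2L) {
    warning("single-row grid: torsional involvement indeterminate")
    torsional <- NA
  } else {
    lo <- ys[1L]; hi <- ys[length(ys)]
    dmax <- max(vapply(xs, function(x) {
      top <- re[grid$x_frac == x & grid$y_frac == hi]
      bot <- re[grid$x_frac == x & grid$y_frac == lo]
      if (!length(top) || !length(bot)) return(0)
      abs(mean(top) - mean(bot))
    }, numeric(1)))
    torsional <- dmax > mixedness
  }
  structure(list(harmonic = harmonic, torsional = torsional,
                 descriptor = if (is.na(torsional)) NA_character_
                              else if (torsional) "mixed" else "flexural"),
            class = "mta_mode_label")
}

#' @export
print.mta_mode_label <- function(x, ...) {
  cat(sprintf("mode label: harmonic %d, %s\n", x$harmonic,
              if (is.na(x$descriptor)) "torsional involvement indeterminate"
              else x$descriptor))
  invisible(x)
}

#' Prominent mode in a frequency band
#'
#' The prominent mode is the mode with the highest spectral magnitude in a
#' given frequency range. The magnitude maximum within the band is matched
#' to the nearest registered mode frequency.
#'
#' @param spectrum data frame with columns `frequency` (Hz) and `magnitude`.
#' @param band numeric length-2, band limits in Hz.
#' @param mode_freqs named numeric vector of registered mode frequencies.
#' @return The name of the prominent mode.
#' @export
prominent_mode <- function(spectrum, band, mode_freqs) {
  stopifnot(is.data.frame(spectrum),
            all(c("frequency", "magnitude") %in% names(spectrum)))
  if (length(band) != 2L || band[2L] <= band[1L]) stop("band must be (lo, hi) with lo < hi")
  inb <- spectrum$frequency >= band[1L] & spectrum$frequency <= band[2L]
  if (!any(inb)) stop("no spectral peak inside the band")
  fpk <- spectrum$frequency[inb][which.max(spectrum$magnitude[inb])]
  names(mode_freqs)[which.min(abs(mode_freqs - fpk))]
}

#' Detect switches of the prominent mode
#'
#' Finds the indices where a time-ordered sequence of prominent-mode labels
#' changes to a new label that persists for at least `debounce_n` samples
#' (shorter excursions are treated as flicker near magnitude crossings and
#' ignored).
#'
#' @param labels character or factor vector of mode labels over time.
#' @param debounce_n minimum persistence, samples.
#' @return Integer vector of switch indices (position of the first sample of
#'   each new persistent label); empty when the label never changes.
#' @examples
#' detect_mode_switches(c("1.1", "1.1", "2", "2", "2", "2"), debounce_n = 3)
#' @export
detect_mode_switches <- function(labels, debounce_n = 3) {
  labels <- as.character(labels)
  if (length(labels) < 2L) stop("need at least 2 labels")
  r <- rle(labels)
  keep <- r$lengths >= debounce_n
  # Collapse flicker: consider only persistent runs, in order.
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  pv <- r$values[keep]; ps <- starts[keep]
  if (!length(pv)) return(integer(0))
  chg <- which(pv[-1L] != pv[-length(pv)])
  ps[chg + 1L]
}

#' Local mass responsivity of a string mode
#'
#' Normalized local mass responsivity at fractional position `x` for
#' harmonic `n`: it scales with the square of the local vibrational
#' amplitude, `sin^2(n*pi*x)` -- zero at the nodes, one at the antinodes.
#'
#' @param x fractional position along the string, in \[0, 1\] (vectorized).
#' @param n harmonic index.
#' @return Responsivity in \[0, 1\].
#' @examples
#' local_responsivity(c(0.25, 0.5), n = 1)
#' @export
local_responsivity <- function(x, n = 1) {
  if (any(x < 0 | x > 1)) stop("x must lie in [0, 1]")
  sin(n * pi * x)^2
}

#' Phase-sweep animation frames of a mode shape
#'
#' Real displacement fields of a grid measurement over one vibration cycle,
#' obtained by superimposing a sinusoidal phase sweep on the measured
#' complex amplitudes (the animation used to assess mode shapes visually).
#'
#' @param grid an [mta_mode_grid][mode_grid()].
#' @param n_frames number of phase steps over one cycle.
#' @return Numeric matrix, `n_frames` rows by `n_points` columns, of real
#'   displacements.
#' @export
mode_animation_frames <- function(grid, n_frames = 24) {
  stopifnot(inherits(grid, "mta_mode_grid"))
  phases <- seq(0, 2 * pi, length.out = n_frames + 1L)[-(n_frames + 1L)]
  t(vapply(seq_along(phases),
           function(k) Re(grid$amplitude * exp(1i * phases[k])),
           numeric(grid$n_points)))
}

#' Write / read a mode grid as CSV
#'
#' The CSV carries columns `x_frac,y_frac,re_amp,im_amp`; the resonance
#' frequency is stored in a leading comment line `# frequency_hz: <value>`.
#'
#' @param grid an `mta_mode_grid`.
#' @param path file path.
#' @return `write_mode_grid` returns `path` invisibly; `read_mode_grid`
#'   returns an `mta_mode_grid`.
#' @export
write_mode_grid <- function(grid, path) {
  stopifnot(inherits(grid, "mta_mode_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frequency_hz: %.6f", grid$frequency), con)
  utils::write.csv(data.frame(x_frac = grid$x_frac, y_frac = grid$y_frac,
                              re_amp = Re(grid$amplitude),
                              im_amp = Im(grid$amplitude)),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mode_grid
#' @export
read_mode_grid <- function(path) {
  first <- readLines(path, n = 1L)
  freq <- as.numeric(sub("^# frequency_hz:\\s*", "", first))
  df <- utils::read.csv(path, comment.char = "#")
  mode_grid(df$x_frac, df$y_frac, complex(real = df$re_amp,
                                          imaginary = df$im_amp), freq)
}
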