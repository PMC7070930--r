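# Three-level contour (particle size class) image analysis.

# Segmentation threshold from a frame: background (median gray level) plus
# half the contrast between the median foreground pixel and the background.
segmentation_threshold <- function(frame) {
  bg <- stats::median(frame)
  span <- max(frame) - bg
  if (span <= 0) return(Inf)           # blank frame: nothing segments
  fg <- frame[frame > bg + 0.25 * span]
  bg + 0.5 * (stats::median(fg) - bg)
}

#' Per-level particle masks of one frame
#'
#' Segments a single 8-bit grayscale frame at a fixed intensity threshold,
#' fills holes, and assigns each connected component to a contour level by
#' its equivalent diameter `2*sqrt(area/pi)/px_per_um` against the level
#' edges (half-open bins `[low, high)`). The default levels separate
#' particles below 5 um, between 5 and 10 um, and above 10 um.
#'
#' @param frame numeric or integer matrix (gray levels 0-255).
#' @param px_per_um image scale, pixels per micrometer.
#' @param level_edges inner bin edges, micrometers.
#' @param threshold segmentation threshold; computed from the frame when
#'   `NULL`.
#' @return List of logical masks, one per level (`length(level_edges) + 1`),
#'   each the union of that level's particles; empty frames give all-empty
#'   masks.
#' @export
contour_levels <- function(frame, px_per_um, level_edges = c(5, 10),
                           threshold = NULL) {
  if (!is.matrix(frame)) stop("frame must be a single-channel matrix")
  if (is.null(threshold)) threshold <- segmentation_threshold(frame)
  nlev <- length(level_edges) + 1L
  masks <- replicate(nlev, matrix(FALSE, nrow(frame), ncol(frame)),
                     simplify = FALSE)
  bin <- frame > threshold
  if (!any(bin)) return(masks)
  lab <- EBImage::bwlabel(EBImage::fillHull(matrix(as.integer(bin),
                                                   nrow(frame), ncol(frame))))
  areas <- tabulate(lab[lab > 0])
  eqd <- 2 * sqrt(areas / pi) / px_per_um
  level <- findInterval(eqd, level_edges) + 1L   # half-open [low, high)
  for (l in seq_len(nlev)) {
    comp <- which(level == l)
    if (length(comp)) masks[[l]] <- matrix(lab %in% comp, nrow(frame))
  }
  masks
}

#' Track per-level pixel areas over a frame stack
#'
#' Counts, frame by frame, the pixels enclosed by the contours of each level
#' (holes filled), then smooths each level's series with the one-period
#' first-order Savitzky-Golay filter. The segmentation threshold is fixed
#' from the first frame so that area changes reflect the particles, not the
#' thresholding.
#'
#' @param stack array `c(height, width, n_frames)` from [render_frames()] or
#'   [read_frames()] (>= 2 frames).
#' @param px_per_um image scale, pixels per micrometer.
#' @param P modulation period, seconds.
#' @param dt time between frames, seconds.
#' @param level_edges inner bin edges, micrometers.
#' @return An object of class `mta_contour_result`: list with `level_edges`,
#'   `areas` (matrix, frame x level, raw pixel counts), `smoothed` (same,
#'   filtered), `temp_C`, `px_per_um`, `P`, `dt`.
#' @export
track_levels <- function(stack, px_per_um, P, dt, level_edges = c(5, 10)) {
  d <- dim(stack)
  if (length(d) != 3L || d[3L] < 2L) stop("need a stack of at least 2 frames")
  thr <- segmentation_threshold(stack[, , 1L])
  nlev <- length(level_edges) + 1L
  areas <- matrix(0, nrow = d[3L], ncol = nlev)
  for (k in seq_len(d[3L])) {
    masks <- contour_levels(stack[, , k], px_per_um, level_edges, thr)
    areas[k, ] <- vapply(masks, sum, numeric(1))
  }
  # One-period window in frames; frame stacks are often sampled more
  # coarsely than P/5, so fall back to the minimum odd window.
  w <- max(5L, round(P / dt))
  if (w %% 2L == 0L) w <- w + 1L
  smoothed <- if (d[3L] > w) {
    apply(areas, 2, signal::sgolayfilt, p = 1, n = w)
  } else {
    areas
  }
  structure(list(level_edges = level_edges, areas = areas,
                 smoothed = smoothed, temp_C = attr(stack, "temp_C"),
                 px_per_um = px_per_um, P = P, dt = dt),
            class = "mta_contour_result")
}

#' Per-level area minima
#'
#' Temperature (and frame index) of each level's global area minimum within
#' the central window of the smoothed series. A level whose series is
#' monotone (minimum at the window boundary) or empty reports no minimum:
#' shrinking-then-spreading particles produce an interior minimum, and the
#' smaller the particles of a level, the closer that minimum sits to the
#' instant quality-factor response.
#'
#' @param result an [track_levels()] result.
#' @param temperature optional temperature series overriding the one stored
#'   in `result`.
#' @param central fraction of the series treated as the central window.
#' @return Data frame with one row per level: `level`, `frame` (NA when
#'   absent), `temp_C` (NA when absent).
#' @export
area_minima <- function(result, temperature = NULL, central = 0.9) {
  stopifnot(inherits(result, "mta_contour_result"))
  temp <- if (is.null(temperature)) result$temp_C else temperature
  n <- nrow(result$smoothed)
  margin <- max(1L, floor(n * (1 - central) / 2))
  win <- seq.int(margin + 1L, n - margin)
  out <- data.frame(level = seq_len(ncol(result$smoothed)),
                    frame = NA_integer_, temp_C = NA_real_)
  for (l in seq_len(ncol(result$smoothed))) {
    s <- result$smoothed[, l]
    if (all(s == 0)) next                       # unpopulated level
    k <- win[which.min(s[win])]
    # Monotone series have their window minimum at a window edge.
    if (k == win[1L] || k == win[length(win)]) next
    out$frame[l] <- k
    if (!is.null(temp)) out$temp_C[l] <- temp[k]
  }
  out
}

#' @export
print.mta_contour_result <- function(x, ...) {
  cat(sprintf("mta_contour_result: %d frames, %d levels (edges %s um)\n",
              nrow(x$areas), ncol(x$areas),
              paste(x$level_edges, collapse = ", ")))
  invisible(x)
}
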