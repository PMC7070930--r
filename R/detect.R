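# Glass-transition detection from the deconvolved signals.

# Local maxima (strict neighbours) of a series; returns indices.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
}

# Topographic prominence of peaks at indices `idx` in series x: height above
# the higher of the two key saddles (lowest point between the peak and the
# nearest higher terrain on each side; series minimum if none).
peak_prominence <- function(x, idx) {
  vapply(idx, function(i) {
    h <- x[i]
    left <- x[seq_len(i - 1L)]
    higher_l <- which(left > h)
    sad_l <- if (length(higher_l)) min(left[(max(higher_l) + 1L):(i - 1L)]) else min(left, h)
    right <- x[(i + 1L):length(x)]
    higher_r <- which(right > h)
    sad_r <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1L)]) else min(right, h)
    h - max(sad_l, sad_r)
  }, numeric(1))
}

#' Reversing-signal maxima
#'
#' Locates prominent local maxima of the reversing signal; the first maximum
#' (lowest temperature) marks the static glass-transition onset Tg_F. A
#' maximum is kept when its topographic prominence is at least
#' `prominence_frac * (max(rs) - median(rs))` and also rises above the
#' envelope noise floor (a calibrated multiple of the robust sub-period
#' ripple scale), so that weakly detuned traces do not report noise ripples as
#' transitions. Pass interior samples only (edge periods excluded);
#' [build_report()] does this automatically.
#'
#' @param rs reversing-signal series (interior samples).
#' @param temperature matching temperature series, degrees C.
#' @param prominence_frac fraction of the signal's dynamic range a maximum
#'   must rise above its surroundings to be reported.
#' @param P,dt optional period and sampling interval used to estimate the
#'   sub-period noise ripple; when `NULL` the noise floor is estimated from
#'   first differences.
#' @return Data frame with columns `temp_C` and `prominence`, ordered by
#'   temperature; zero rows when no maximum passes the rule.
#' @export
rs_maxima <- function(rs, temperature, prominence_frac = 0.2,
                      P = NULL, dt = NULL) {
  if (length(rs) != length(temperature)) stop("series lengths differ")
  ok <- is.finite(rs)
  x <- rs[ok]; temp <- temperature[ok]
  idx <- local_maxima(x)
  if (!length(idx)) return(data.frame(temp_C = numeric(0), prominence = numeric(0)))
  prom <- peak_prominence(x, idx)
  # Noise floor: for white measurement noise passed through the envelope /
  # one-period-smoothing chain, the prominence of spurious period-scale
  # bumps is an essentially fixed multiple (~12x) of the robust SD of the
  # sub-period residual; 20x adds a safety margin. Residual about a
  # one-period smooth when the period is known, otherwise lag-1 differences.
  ripple <- if (!is.null(P) && !is.null(dt) && length(x) > sg_window(P, dt)) {
    x - signal::sgolayfilt(x, p = 1, n = sg_window(P, dt))
  } else {
    diff(x) / sqrt(2)
  }
  noise_floor <- 20 * stats::mad(ripple, center = 0)
  thr <- max(prominence_frac * (max(x) - stats::median(x)), noise_floor)
  keep <- prom >= thr & thr > 0
  out <- data.frame(temp_C = temp[idx[keep]], prominence = prom[keep])
  out[order(out$temp_C), , drop = FALSE]
}

#' Quality-factor transition temperature (Tg_Q)
#'
#' Detects the dynamic (liquefaction) glass transition from a smoothed
#' quality-factor trace. When a prominent local minimum exists it is
#' returned directly (`method = "minimum"`). A quality factor without a
#' pronounced minimum still shifts toward higher values at the transition;
#' in that case the intersection of the pre-rise baseline tangent with the
#' maximum-slope tangent is returned (`method = "rise-onset"`). The input is
#' expected to be smoothed with the one-period filter ([underlying_signal()]).
#'
#' @param quality smoothed quality-factor series.
#' @param temperature matching temperature series, degrees C.
#' @param prominence_frac fraction of the Q range a minimum must be
#'   prominent by to count as pronounced.
#' @return List with `temp_C` and `method` (`"minimum"` or `"rise-onset"`).
#' @export
quality_transition <- function(quality, temperature, prominence_frac = 0.2) {
  if (length(quality) != length(temperature)) stop("series lengths differ")
  rng <- max(quality) - min(quality)
  if (rng == 0) stop("no transition: quality factor is constant")
  neg <- -quality
  idx <- local_maxima(neg)
  if (length(idx)) {
    prom <- peak_prominence(neg, idx)
    keep <- prom >= prominence_frac * rng
    if (any(keep)) {
      best <- idx[keep][which.max(prom[keep])]
      return(list(temp_C = temperature[best], method = "minimum"))
    }
  }
  # Rise-onset fallback: tangent construction on the monotone rise.
  slope <- diff(quality) / diff(temperature)
  if (all(slope <= 0)) stop("no transition: quality factor decreases throughout")
  k <- which.max(slope)
  # Pre-rise baseline: fit a line over samples well before the rise, where
  # the local slope is below 10% of the maximum slope.
  pre <- which(seq_along(slope) < k & slope < 0.1 * slope[k])
  if (length(pre) < 2L) pre <- seq_len(max(2L, floor(k / 2)))
  base_fit <- stats::lm.fit(cbind(1, temperature[pre]), quality[pre])
  a0 <- base_fit$coefficients[1L]; b0 <- base_fit$coefficients[2L]
  tk <- (temperature[k] + temperature[k + 1L]) / 2
  qk <- (quality[k] + quality[k + 1L]) / 2
  bk <- slope[k]
  a1 <- qk - bk * tk
  list(temp_C = unname((a1 - a0) / (b0 - bk)), method = "rise-onset")
}

#' Onset and maximum detuning of the underlying frequency signal
#'
#' Locates the initial slope change of the UFS and the maximum detuning.
#' A provisional pre-transition baseline is fitted to the first quarter of
#' the samples; the analysis window runs from the start of the series to the
#' first sample approaching the maximum deviation from that baseline (the
#' maximum-detuning point), so that a transition which completes and then
#' runs parallel to the old baseline is still dated at its initial slope
#' change rather than at its midpoint. Within that window a continuous
#' two-segment piecewise-linear model is fitted by least squares over a
#' scan of candidate breakpoints (coarse-to-fine; ties broken toward lower
#' temperature, onset semantics). The breakpoint is the transition onset;
#' the detuning is the largest deviation of the full UFS from the
#' pre-transition line refitted over temperatures up to the onset. When the
#' two-segment fit does not improve on a single line by at least
#' `min_improvement` (fractional reduction in residual sum of squares), no
#' onset is reported and the detuning is `NA` -- a trace without pronounced
#' detuning.
#'
#' @param ufs underlying frequency signal, Hz (interior samples).
#' @param temperature matching temperature series, degrees C.
#' @param min_improvement minimum fractional RSS reduction over a single
#'   straight line for an onset to be declared.
#' @return List with `onset_C` (degrees C or `NA`) and `detuning_Hz`
#'   (maximum deviation from the pre-transition line, Hz, or `NA`).
#' @export
ufs_onset_and_detuning <- function(ufs, temperature, min_improvement = 0.25) {
  n <- length(ufs)
  if (n != length(temperature)) stop("series lengths differ")
  if (n < 20L) stop("series too short for a breakpoint scan")

  # Provisional baseline from the first quarter; window up to the first
  # approach (95%) of the maximum deviation.
  pre_n <- max(10L, floor(n / 4))
  base0 <- stats::lm.fit(cbind(1, temperature[seq_len(pre_n)]),
                         ufs[seq_len(pre_n)])$coefficients
  dev <- abs(ufs - (base0[1L] + base0[2L] * temperature))
  istar <- which(dev >= 0.95 * max(dev))[1L]
  win <- seq_len(max(istar, 20L))
  tw <- temperature[win]; yw <- ufs[win]
  m <- length(win)

  # Candidate breakpoints: central 80% of the window.
  lo <- stats::quantile(tw, 0.10); hi <- stats::quantile(tw, 0.90)
  cand <- which(tw >= lo & tw <= hi)
  if (length(cand) < 5L) stop("too few candidate breakpoints")
  X1 <- cbind(1, tw)
  rss1 <- sum(stats::lm.fit(X1, yw)$residuals^2)
  rss_at <- function(i) {
    hinge <- pmax(tw - tw[i], 0)
    sum(stats::lm.fit(cbind(X1, hinge), yw)$residuals^2)
  }
  step <- max(1L, floor(length(cand) / 200L))
  coarse <- cand[seq(1L, length(cand), by = step)]
  rss_c <- vapply(coarse, rss_at, numeric(1))
  i0 <- coarse[which.min(rss_c)]
  fine <- cand[cand >= i0 - step & cand <= i0 + step]
  rss_f <- vapply(fine, rss_at, numeric(1))
  # Tie toward lower temperature: first index attaining the minimum.
  best <- fine[which(rss_f == min(rss_f))[1L]]
  rss2 <- min(rss_f)

  if (rss1 <= 0 || (rss1 - rss2) / rss1 < min_improvement) {
    return(list(onset_C = NA_real_, detuning_Hz = NA_real_))
  }
  # Refit the pre-transition line with a small margin below the onset so the
  # leading tail of the transition does not bias the extrapolation.
  margin <- 0.1 * (tw[best] - temperature[1L])
  pre <- temperature <= tw[best] - margin
  if (sum(pre) < 10L) pre <- temperature <= tw[best]
  fit <- stats::lm.fit(cbind(1, temperature[pre]), ufs[pre])
  pred <- fit$coefficients[1L] + fit$coefficients[2L] * temperature
  list(onset_C = tw[best],
       detuning_Hz = max(abs(ufs - pred)))
}

#' Assemble a glass-transition report
#'
#' Runs the three detectors on a deconvolved measurement and collects the
#' results: Tg_F (first reversing-signal maximum), Tg_Q (quality-factor
#' transition), the UFS slope-change onset and maximum detuning, and their
#' difference `delta_qf = tg_q - tg_f`. Edge periods of the deconvolution
#' are excluded before detection, and the quality factor is smoothed with
#' the one-period filter.
#'
#' @param deconv an [deconvolve()] result.
#' @param quality raw quality-factor series for the same mode.
#' @param prominence_frac passed to [rs_maxima()] and [quality_transition()].
#' @return An object of class `mta_tg_report`: list with `tg_f`, `rs_maxima`
#'   (data frame), `tg_q`, `tg_q_method`, `ufs_onset`, `delta_qf`,
#'   `detuning`, and character vector `flags` (possibly empty; e.g.
#'   `"multiple-maxima"` when more than one RS maximum is present,
#'   `"no-rs-maximum"` when none is).
#' @export
build_report <- function(deconv, quality, prominence_frac = 0.2) {
  stopifnot(inherits(deconv, "mta_deconvolution"))
  keep <- !deconv$edge
  temp <- deconv$temperature[keep]
  mx <- rs_maxima(deconv$rs[keep], temp, prominence_frac,
                  P = deconv$P, dt = deconv$dt)
  flags <- character(0)
  if (nrow(mx) > 1L) flags <- c(flags, "multiple-maxima")
  if (nrow(mx) == 0L) flags <- c(flags, "no-rs-maximum")
  tg_f <- if (nrow(mx)) mx$temp_C[1L] else NA_real_

  q_sm <- underlying_signal(quality, deconv$P, deconv$dt)[keep]
  qt <- tryCatch(quality_transition(q_sm, temp, prominence_frac),
                 error = function(e) list(temp_C = NA_real_, method = "none"))
  onset <- ufs_onset_and_detuning(deconv$ufs[keep], temp)
  structure(list(tg_f = tg_f, rs_maxima = mx,
                 tg_q = qt$temp_C, tg_q_method = qt$method,
                 ufs_onset = onset$onset_C,
                 delta_qf = qt$temp_C - tg_f,
                 detuning = onset$detuning_Hz,
                 flags = flags, mode_id = deconv$mode_id),
            class = "mta_tg_report")
}

#' @export
print.mta_tg_report <- function(x, ...) {
  cat("Glass-transition report (mode", x$mode_id, ")\n")
  cat(sprintf("  Tg_F (reversing signal): %.2f degC\n", x$tg_f))
  cat(sprintf("  Tg_Q (%s):               %.2f degC\n", x$tg_q_method, x$tg_q))
  cat(sprintf("  Tg_Q - Tg_F:             %.2f degC\n", x$delta_qf))
  cat(sprintf("  UFS onset:               %.2f degC\n", x$ufs_onset))
  cat(sprintf("  max detuning:            %.1f Hz\n", x$detuning))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
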