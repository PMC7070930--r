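#' Underlying (non-periodic) signal by Savitzky-Golay filtering
#'
#' Removes the applied temperature modulation from a raw trace with a
#' first-order Savitzky-Golay filter whose frame length corresponds to one
#' modulation period (nearest odd number of samples). Endpoints are handled
#' by the filter's polynomial edge fits, so the output has the same length
#' as the input. The filter preserves constants and straight lines exactly
#' and strongly attenuates period-`P` sinusoids.
#'
#' @param raw numeric series (e.g. resonance frequency, Hz).
#' @param P modulation period, seconds.
#' @param dt sampling interval, seconds (`P/dt >= 5`).
#' @return Smoothed series, same length as `raw`.
#' @export
underlying_signal <- function(raw, P, dt) {
  w <- sg_window(P, dt)
  if (length(raw) <= w) stop("series shorter than the filter window")
  signal::sgolayfilt(raw, p = 1, n = w)
}

# Analytic signal via the Fourier-domain Hilbert construction: zero the
# negative-frequency half of the spectrum and double the positive half.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Upper envelope of a periodic signal
#'
#' Amplitude demodulation of the periodic part of a modulated trace: the
#' magnitude of the Fourier-domain analytic signal (Hilbert envelope),
#' smoothed with the same one-period first-order Savitzky-Golay filter used
#' for the underlying signal. For a pure sinusoid the interior envelope is
#' its amplitude; the first and last period carry edge artifacts and should
#' be ignored by downstream detectors.
#'
#' @param periodic zero-mean periodic series (raw minus underlying signal).
#' @param P modulation period, seconds.
#' @param dt sampling interval, seconds.
#' @return Non-negative envelope series, same length as input.
#' @export
upper_envelope <- function(periodic, P, dt) {
  w <- sg_window(P, dt)
  if (length(periodic) <= w) stop("series shorter than the filter window")
  env <- Mod(analytic_signal(periodic))
  pmax(signal::sgolayfilt(env, p = 1, n = w), 0)
}

#' Reversing signal
#'
#' Normalizes the upper envelope of the periodic frequency response by the
#' envelope of the applied temperature modulation and the period:
#' \deqn{RS(t) = \frac{P_{ue}(t)}{TS_{ue}(t) \cdot P / (2\pi)}}
#' For a trace responding linearly to temperature with slope `c`, the
#' reversing signal is constant at `|c| * 2*pi / P`; transient responses
#' (e.g. the onset of glass-transition detuning) appear as local maxima.
#'
#' @param p_ue upper envelope of the periodic part of the response.
#' @param ts_ue upper envelope of the temperature modulation, degrees C.
#' @param P modulation period, seconds.
#' @return Reversing-signal series; samples where `ts_ue <= 0` are `NA`
#'   (masked with a warning).
#' @export
reversing_signal <- function(p_ue, ts_ue, P) {
  if (length(p_ue) != length(ts_ue)) stop("envelope series lengths differ")
  bad <- ts_ue <= 0
  rs <- p_ue / (ts_ue * P / (2 * pi))
  if (any(bad)) {
    warning(sprintf("%d sample(s) with non-positive temperature envelope masked",
                    sum(bad)))
    rs[bad] <- NA_real_
  }
  rs
}

#' Dominant frequency of a modulated trace
#'
#' Detrends the series by first-differencing (a straight line becomes a
#' constant and is removed with the mean, and slowly varying components such
#' as glass-transition detuning are strongly suppressed, while a periodic
#' component keeps its frequency bin exactly), normalizes to unit variance,
#' and returns the frequency of the maximum of the FFT magnitude over the
#' positive-frequency bins. Used to verify the direct transfer of the
#' applied modulation period into the resonance-frequency response (a 20 s
#' period shows up as a 0.050 Hz maximum).
#'
#' @param raw numeric series containing at least 10 modulation cycles.
#' @param dt sampling interval, seconds.
#' @return Frequency of the spectral maximum, Hz.
#' @export
dominant_frequency <- function(raw, dt) {
  if (length(raw) < 20L) stop("series too short")
  d <- diff(raw)
  d <- d - mean(d)
  s <- stats::sd(d)
  if (!is.finite(s) || s == 0) stop("no periodic component: series is flat after detrending")
  x <- d / s
  n <- length(x)
  mag <- Mod(stats::fft(x))
  half <- 2:(floor(n / 2) + 1L)     # exclude DC
  k <- half[which.max(mag[half])] - 1L
  k / (n * dt)
}

#' Deconvolve a modulated measurement
#'
#' Runs the full deconvolution chain on one tracked mode of a measurement:
#' underlying frequency signal (UFS) by one-period Savitzky-Golay filtering,
#' periodic part as `raw - UFS` (so `UFS + periodic == raw` exactly), Hilbert
#' upper envelopes of the periodic frequency part and of the temperature
#' modulation, and the reversing signal. The first and last full period are
#' flagged as edge samples; detectors ignore them.
#'
#' @param measurement an [simulate_measurement()] result or a measurement
#'   loaded with [load_trace()].
#' @param mode_id tracked mode to deconvolve (default: first mode).
#' @param P modulation period, seconds; defaults to the measurement's
#'   program period when available.
#' @return An object of class `mta_deconvolution`: list with `time`,
#'   `temperature`, `raw`, `ufs`, `periodic`, `p_ue`, `ts_ue`, `rs`, `edge`
#'   (logical), `P`, `dt`, `mode_id`, and the measurement's `truth` (if any).
#' @examples
#' m <- simulate_measurement(string_model(), tg_scenario(), temperature_program(),
#'                           duration = 600, dt = 0.2)
#' d <- deconvolve(m)
#' range(d$rs[!d$edge])
#' @export
deconvolve <- function(measurement, mode_id = NULL, P = NULL) {
  stopifnot(inherits(measurement, "mta_measurement"))
  if (is.null(mode_id)) mode_id <- measurement$mode_ids[1L]
  if (!mode_id %in% measurement$mode_ids) {
    stop(sprintf("mode '%s' not present; available: %s", mode_id,
                 paste(measurement$mode_ids, collapse = ", ")))
  }
  if (is.null(P)) {
    P <- if (!is.null(measurement$program)) measurement$program$P else 20
  }
  dt <- measurement$dt
  raw <- measurement$freq[[mode_id]]
  ufs <- underlying_signal(raw, P, dt)
  periodic <- raw - ufs
  p_ue <- upper_envelope(periodic, P, dt)
  temp <- measurement$temperature
  ts_per <- temp - underlying_signal(temp, P, dt)
  ts_ue <- upper_envelope(ts_per, P, dt)
  rs <- reversing_signal(p_ue, ts_ue, P)
  n <- length(raw)
  edge <- rep(TRUE, n)
  edge[interior_index(n, P, dt)] <- FALSE
  structure(list(time = measurement$time, temperature = temp, raw = raw,
                 ufs = ufs, periodic = periodic, p_ue = p_ue, ts_ue = ts_ue,
                 rs = rs, edge = edge, P = P, dt = dt, mode_id = mode_id,
                 truth = measurement$truth),
            class = "mta_deconvolution")
}

#' @export
print.mta_deconvolution <- function(x, ...) {
  cat(sprintf("mta_deconvolution of '%s': %d samples, P = %g s, dt = %g s\n",
              x$mode_id, length(x$raw), x$P, x$dt))
  cat(sprintf("  interior RS range: %.3f to %.3f\n",
              min(x$rs[!x$edge], na.rm = TRUE), max(x$rs[!x$edge], na.rm = TRUE)))
  invisible(x)
}

#' Convert a deconvolution result to a data frame
#'
#' @param x an `mta_deconvolution` object.
#' @param ... unused.
#' @return Data frame with columns `time_s`, `temp_C`, `raw`, `ufs`,
#'   `periodic`, `p_ue`, `ts_ue`, `rs`, `edge`.
#' @export
as.data.frame.mta_deconvolution <- function(x, ...) {
  data.frame(time_s = x$time, temp_C = x$temperature, raw = x$raw,
             ufs = x$ufs, periodic = x$periodic, p_ue = x$p_ue,
             ts_ue = x$ts_ue, rs = x$rs, edge = x$edge)
}
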