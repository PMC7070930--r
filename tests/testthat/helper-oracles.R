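# Shared fixtures and independent oracles.

default_time <- function(duration = 1500, dt = 0.2) seq(0, duration, by = dt)

# Per-cycle maxima envelope oracle: the amplitude of each complete
# modulation cycle estimated brute-force as the maximum of |x| within the
# cycle, placed at the cycle center. Independent of the Hilbert construction.
cycle_maxima_envelope <- function(x, t, P) {
  cyc <- floor(t / P)
  n_per <- table(cyc)
  full <- as.integer(names(n_per)[n_per == max(n_per)])
  keep <- cyc %in% full
  cyc <- cyc[keep]
  data.frame(
    t_mid = as.numeric(tapply(t[keep], cyc, mean)),
    amp = as.numeric(tapply(abs(x[keep]), cyc, max))
  )
}

# Brute-force foreground pixel count of a rendered frame at the
# segmentation threshold used by the analysis.
brute_pixel_count <- function(frame, background, brightness) {
  sum(frame > background + 0.5 * (brightness - background) / 2 + background * 0)
}

# Cache expensive default-scenario reports across test files.
.report_cache <- new.env(parent = emptyenv())
cached_default_report <- function(seed) {
  key <- as.character(seed)
  if (is.null(.report_cache[[key]])) {
    m <- simulate_bundle(make_scenario("indomethacin_default", seed = seed))
    d <- deconvolve(m)
    .report_cache[[key]] <- build_report(d, m$quality[[1L]])
  }
  .report_cache[[key]]
}
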