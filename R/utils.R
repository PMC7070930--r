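# Internal helpers shared across modules.

# Nearest odd integer to P/dt; Savitzky-Golay windows must be odd.
# Ties (even P/dt) round up so the window always spans >= one period.
sg_window <- function(P, dt) {
  w <- round(P / dt)
  if (w < 5L) stop("modulation period must span at least 5 samples (P/dt >= 5)")
  if (w %% 2L == 0L) w <- w + 1L
  as.integer(w)
}

logistic <- function(x) stats::plogis(x)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate `code` under a fixed, algorithm-stable RNG stream and restore
# the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  }
  invisible(x)
}

# Indices of the interior samples: everything but the first and last full
# modulation period, where envelope edge artifacts live.
interior_index <- function(n, P, dt) {
  k <- ceiling(P / dt)
  if (2L * k >= n) stop("series shorter than two modulation periods")
  seq.int(k + 1L, n - k)
}
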