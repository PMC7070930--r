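#' Glass-transition scenario (simulation ground truth)
#'
#' Parameters of the simulated glass transition that a measurement embeds as
#' ground truth. The static onset `tg_static` is where the resonance
#' frequency starts to detune (first reversing-signal maximum); the dynamic
#' transition `tg_dynamic` is where viscous flow sets in, marked by the
#' quality-factor minimum followed by a sharp rise.
#'
#' @param tg_static static (thermal) onset temperature, degrees C.
#' @param tg_dynamic dynamic (liquefaction) transition temperature, degrees
#'   C; must be >= `tg_static`.
#' @param detune_total maximum frequency detuning during the transition, Hz.
#' @param two_step if `TRUE` the detuning happens in two logistic steps, one
#'   at `tg_static` and one at `tg_dynamic` (half the total each), emulating
#'   the two-fold frequency change seen for large effective-mass
#'   redistributions.
#' @param step_width temperature width of each logistic step, degrees C.
#' @param q0 baseline quality factor.
#' @param q_dip depth of the quality-factor dip at `tg_dynamic`.
#' @param q_rise quality-factor increase after liquefaction.
#' @param noise_f frequency noise standard deviation, Hz.
#' @param noise_q quality-factor noise standard deviation.
#' @param responsivity per-mode multiplier(s) on the detuning step, recycled
#'   over the tracked modes; mixed (torsional-involved) modes respond more
#'   strongly than flexural ones.
#' @param seed integer seed for the noise stream.
#' @return An object of class `mta_scenario`.
#' @export
tg_scenario <- function(tg_static = 45, tg_dynamic = 50, detune_total = 300,
                        two_step = FALSE, step_width = 0.5,
                        q0 = 2000, q_dip = 400, q_rise = 600,
                        noise_f = 0.5, noise_q = 8,
                        responsivity = 1, seed = 1L) {
  if (tg_dynamic < tg_static) stop("tg_dynamic must be >= tg_static")
  if (q0 <= 0) stop("q0 must be positive")
  if (q0 - q_dip <= 0) stop("q0 - q_dip must stay positive")
  if (noise_f < 0 || noise_q < 0) stop("noise standard deviations must be >= 0")
  if (step_width <= 0) stop("step_width must be positive")
  if (detune_total < 0) stop("detune_total must be >= 0")
  structure(list(tg_static = tg_static, tg_dynamic = tg_dynamic,
                 detune_total = detune_total, two_step = isTRUE(two_step),
                 step_width = step_width, q0 = q0, q_dip = q_dip,
                 q_rise = q_rise, noise_f = noise_f, noise_q = noise_q,
                 responsivity = responsivity, seed = as.integer(seed)),
            class = "mta_scenario")
}

# Noise-free detuning (Hz, <= 0) as a function of temperature. One logistic
# step centered at the static onset; with two_step, the total detuning is
# split evenly between steps at tg_static and tg_dynamic.
detune_curve <- function(scenario, temp) {
  sw <- scenario$step_width
  if (scenario$two_step) {
    -scenario$detune_total / 2 *
      (logistic((temp - scenario$tg_static) / sw) +
         logistic((temp - scenario$tg_dynamic) / sw))
  } else {
    -scenario$detune_total * logistic((temp - scenario$tg_static) / sw)
  }
}

# Noise-free quality factor vs temperature: Gaussian dip centered at
# tg_dynamic (width = step_width) and a sharp rise logistic centered at
# tg_dynamic + 2*step_width with width step_width/2, so the minimum of the
# combined curve sits at tg_dynamic to within a few hundredths of a degree.
quality_curve <- function(scenario, temp) {
  sw <- scenario$step_width
  scenario$q0 -
    scenario$q_dip * exp(-(temp - scenario$tg_dynamic)^2 / (2 * sw^2)) +
    scenario$q_rise * logistic((temp - scenario$tg_dynamic - 2 * sw) / (sw / 2))
}

#' Simulate a modulated MTA measurement
#'
#' Generates synchronized time / temperature / per-mode resonance-frequency /
#' quality-factor traces for a string carrying a glass-forming sample under a
#' modulated heating program. Each mode responds instantaneously to the
#' modulated temperature `T(t)`:
#' \deqn{f_n(t) = f_{n,loaded} + c_T (T(t) - T_0) + r_n\, \Delta f(T(t)) + \epsilon}
#' where \eqn{\Delta f} is the logistic detuning of the scenario and
#' \eqn{r_n} the per-mode responsivity, so the applied modulation transfers
#' to the frequency trace with the local slope \eqn{|c_T + \Delta f'(T)|}.
#' The quality factor follows the scenario's dip-then-rise curve evaluated at
#' `T(t)`. Identical seeds give bit-identical measurements.
#'
#' @param string a [string_model()].
#' @param scenario a [tg_scenario()].
#' @param program a [temperature_program()].
#' @param duration total duration, seconds. The default spans the 30-70
#'   degrees C window at the default 1.6 C/min ramp.
#' @param dt sampling interval, seconds.
#' @param particles list of [particle()] objects loading the string.
#' @param distributed_mass reference distributed load, ng.
#' @param modes optional data frame overriding the default harmonic ladder,
#'   with columns `id`, `harmonic`, and optionally `freq_factor` (multiplier
#'   on `harmonic * f1`, used for mixed modes that sit off the flexural
#'   ladder). Responsivities come from `scenario$responsivity`, recycled.
#' @return An object of class `mta_measurement`: list with `time`,
#'   `temperature`, `freq` (named list per mode), `quality` (named list per
#'   mode), `mode_ids`, `dt`, `program`, and the embedded `truth` scenario.
#' @examples
#' m <- simulate_measurement(string_model(), tg_scenario(), temperature_program(),
#'                           duration = 300, dt = 0.2)
#' str(m$freq)
#' @export
simulate_measurement <- function(string, scenario, program,
                                 duration = 1500, dt = 0.2,
                                 particles = list(), distributed_mass = 0,
                                 modes = NULL) {
  stopifnot(inherits(string, "mta_string"),
            inherits(scenario, "mta_scenario"),
            inherits(program, "mta_program"))
  tr <- generate_temperature(program, duration, dt)
  t <- tr$time_s
  temp <- tr$temp_C
  if (scenario$tg_static > max(temp) || scenario$tg_dynamic < min(temp)) {
    warning("glass-transition window lies outside the temperature range; ",
            "traces produced without a transition signature")
  }
  if (is.null(modes)) {
    modes <- data.frame(id = paste0("mode", seq_len(string$n_modes)),
                        harmonic = seq_len(string$n_modes),
                        freq_factor = 1)
    if (string$n_modes >= 1L) modes$id[1L] <- "mode1"
  }
  if (is.null(modes$freq_factor)) modes$freq_factor <- 1
  resp <- rep_len(scenario$responsivity, nrow(modes))

  freq <- vector("list", nrow(modes))
  quality <- vector("list", nrow(modes))
  names(freq) <- names(quality) <- modes$id
  qc <- quality_curve(scenario, temp)
  with_seed(scenario$seed, {
    for (i in seq_len(nrow(modes))) {
      base <- loaded_mode_frequency(string, particles, modes$harmonic[i],
                                    distributed_mass) * modes$freq_factor[i]
      f <- base + string$c_T * (temp - program$T0) +
        resp[i] * detune_curve(scenario, temp)
      if (scenario$noise_f > 0) f <- f + stats::rnorm(length(f), 0, scenario$noise_f)
      q <- qc
      if (scenario$noise_q > 0) q <- q + stats::rnorm(length(q), 0, scenario$noise_q)
      freq[[i]] <- f
      quality[[i]] <- q
    }
  })
  structure(list(time = t, temperature = temp, freq = freq, quality = quality,
                 mode_ids = modes$id, dt = dt, program = program,
                 truth = scenario),
            class = "mta_measurement")
}

#' @export
print.mta_measurement <- function(x, ...) {
  cat(sprintf("mta_measurement: %d samples, dt = %g s, %.1f-%.1f degC, modes: %s\n",
              length(x$time), x$dt, min(x$temperature), max(x$temperature),
              paste(x$mode_ids, collapse = ", ")))
  invisible(x)
}
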