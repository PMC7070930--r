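#' Modulated heating program
#'
#' Describes the temperature-modulated heating protocol used in modulated
#' micromechanical thermal analysis: a linear underlying ramp with a
#' superimposed sinusoid, realized by pulse-width modulation (PWM) of a
#' Peltier element. The PWM duty-cycle law is
#' \deqn{DC(t) = k_s + k_l t + A_{mod} \sin(2\pi t / P)}
#' and its temperature-space realization (assumed linear in duty) is
#' \deqn{T(t) = T_0 + (\mathrm{rate}/60)\, t + a_T \sin(2\pi t / P).}
#'
#' @param T0 start temperature, degrees C.
#' @param rate underlying heating rate, degrees C per minute.
#' @param amp_T realized temperature modulation amplitude, degrees C.
#' @param P modulation period, seconds.
#' @param ks minimum duty-cycle constant (heater-dependent), dimensionless.
#' @param kl linear duty-cycle slope, per second.
#' @param A_mod duty-space modulation amplitude, dimensionless.
#' @return An object of class `mta_program`.
#' @examples
#' prog <- temperature_program()
#' duty_cycle(prog, c(0, 5, 10))
#' @export
temperature_program <- function(T0 = 30, rate = 1.6, amp_T = 0.2, P = 20,
                                ks = 0.1, kl = 2e-4, A_mod = 0.02) {
  stopifnot_scalar(T0, "T0"); stopifnot_scalar(rate, "rate")
  stopifnot_scalar(amp_T, "amp_T"); stopifnot_scalar(P, "P")
  if (P <= 0) stop("invalid program: modulation period P must be positive")
  if (rate <= 0) stop("invalid program: heating rate must be positive")
  if (amp_T < 0) stop("invalid program: modulation amplitude must be >= 0")
  structure(list(T0 = T0, rate = rate, amp_T = amp_T, P = P,
                 ks = ks, kl = kl, A_mod = A_mod),
            class = "mta_program")
}

#' PWM duty cycle of the heating program
#'
#' Evaluates the duty-cycle law \eqn{DC(t) = k_s + k_l t + A_{mod}\sin(2\pi t/P)},
#' clamped to the physically admissible range \[0, 1\].
#'
#' @param program an [temperature_program()] object.
#' @param t time, seconds (vectorized, must be >= 0).
#' @return Duty fraction(s) in \[0, 1\].
#' @export
duty_cycle <- function(program, t) {
  stopifnot(inherits(program, "mta_program"))
  if (any(t < 0)) stop("t must be >= 0")
  dc <- program$ks + program$kl * t +
    sin(2 * pi * t / program$P) * program$A_mod
  clamp(dc, 0, 1)
}

#' Generate the modulated temperature trace
#'
#' Realizes the heating program in temperature space at a fixed sampling
#' interval: `T(t) = T0 + (rate/60)*t + amp_T*sin(2*pi*t/P)`.
#'
#' @param program an [temperature_program()] object.
#' @param duration total duration, seconds.
#' @param dt sampling interval, seconds. Must resolve the modulation
#'   (`dt < P/2`), otherwise an aliasing error is raised.
#' @return A data frame with columns `time_s` and `temp_C`
#'   (`floor(duration/dt) + 1` rows).
#' @examples
#' tr <- generate_temperature(temperature_program(), duration = 100, dt = 0.2)
#' head(tr)
#' @export
generate_temperature <- function(program, duration, dt = 0.2) {
  stopifnot(inherits(program, "mta_program"))
  stopifnot_scalar(duration, "duration"); stopifnot_scalar(dt, "dt")
  if (duration <= 0 || dt <= 0) stop("duration and dt must be positive")
  if (dt >= program$P / 2) {
    stop(sprintf("aliasing: dt = %g s cannot resolve a %g s modulation period",
                 dt, program$P))
  }
  t <- seq(0, by = dt, length.out = floor(duration / dt) + 1L)
  temp <- program$T0 + (program$rate / 60) * t +
    program$amp_T * sin(2 * pi * t / program$P)
  data.frame(time_s = t, temp_C = temp)
}
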