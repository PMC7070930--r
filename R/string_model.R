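#' Microstring resonator model
#'
#' Geometry and resonance properties of a silicon-rich nitride (SiRN)
#' microstring. An unloaded string has an exact harmonic ladder
#' \eqn{f_n = n f_1}; deposited sample mass detunes the modes according to
#' the mode-shape-weighted effective load (see [loaded_mode_frequency()]).
#'
#' @param L string length, micrometers.
#' @param m0 string mass, nanograms.
#' @param f1 fundamental resonance frequency at the start temperature, Hz.
#' @param c_T temperature responsivity of the resonance frequency, Hz per
#'   degree C. Negative by default: heating relaxes the tensile stress of the
#'   string against its frame, so frequency falls with temperature.
#' @param n_modes number of tracked harmonics.
#' @return An object of class `mta_string`.
#' @examples
#' s <- string_model()
#' loaded_mode_frequency(s, list(), n = 3) / loaded_mode_frequency(s, list(), n = 1)
#' @export
string_model <- function(L = 800, m0 = 23, f1 = 163e3, c_T = -30, n_modes = 1) {
  stopifnot_scalar(f1, "f1"); stopifnot_scalar(m0, "m0")
  if (f1 <= 0) stop("f1 must be positive")
  if (m0 <= 0) stop("m0 must be positive")
  if (L <= 0) stop("L must be positive")
  if (n_modes < 1) stop("n_modes must be >= 1")
  structure(list(L = L, m0 = m0, f1 = f1, c_T = c_T,
                 n_modes = as.integer(n_modes)),
            class = "mta_string")
}

#' Sample particle on a string
#'
#' @param x fractional position along the string length, in \[0, 1\].
#' @param mass particle mass, nanograms.
#' @param diameter particle diameter, micrometers.
#' @return A `list` of class `mta_particle`.
#' @export
particle <- function(x, mass, diameter) {
  if (x < 0 || x > 1) stop("x must lie in [0, 1]")
  if (mass <= 0) stop("mass must be positive")
  if (diameter <= 0) stop("diameter must be positive")
  structure(list(x = x, mass = mass, diameter = diameter),
            class = "mta_particle")
}

# Mode-shape weighted effective load, ng. Point masses are weighted by
# 2*sin^2(n*pi*x): the local mass responsivity scales with the square of the
# local vibrational amplitude, and the factor 2 normalizes the weight so a
# load spread uniformly along the string contributes its full mass
# (mean of 2*sin^2 over a period is 1). `distributed_mass` is the reference
# distributed load and enters with weight exactly 1.
effective_load <- function(particles, n, distributed_mass = 0) {
  w <- vapply(particles, function(p) 2 * sin(n * pi * p$x)^2 * p$mass,
              numeric(1))
  distributed_mass + sum(w)
}

#' Resonance frequency of a loaded mode
#'
#' Frequency of harmonic `n` of a string carrying point particles and/or a
#' reference distributed load. The unloaded ladder is exact
#' (\eqn{f_n = n f_1}); loading detunes each mode through its effective mass
#' \eqn{m_{eff}}, with each point particle weighted by
#' \eqn{2\sin^2(n\pi x)} (zero at the nodes, maximal at the antinodes).
#' The frequency-load relation is the exact inverse of the mass
#' approximation used by [estimate_sample_mass()]:
#' \deqn{f_n = n f_1 \sqrt{\frac{\pi m_0}{\pi m_0 + (\pi + 2) m_{eff}}}}
#' so that mass estimation round-trips exactly for a distributed load.
#'
#' @param string a [string_model()].
#' @param particles list of [particle()] objects (may be empty).
#' @param n harmonic index, >= 1.
#' @param distributed_mass mass of a uniformly distributed reference load,
#'   nanograms.
#' @return Resonance frequency, Hz.
#' @export
loaded_mode_frequency <- function(string, particles = list(), n = 1,
                                  distributed_mass = 0) {
  stopifnot(inherits(string, "mta_string"))
  if (n < 1) stop("harmonic index n must be >= 1")
  meff <- effective_load(particles, n, distributed_mass)
  n * string$f1 *
    sqrt(pi * string$m0 / (pi * string$m0 + (pi + 2) * meff))
}

#' Approximate deposited sample mass from resonance detuning
#'
#' Estimates the sample mass on a string from the resonance frequency of the
#' unloaded string (`f0`), of the loaded string (`f_res`), and the string
#' mass `m0`, for a distributed sample load:
#' \deqn{m_{sample} = \frac{\pi m_0 (f_0^2 - f_{res}^2)}{(\pi + 2) f_{res}^2}}
#'
#' @param f0 unloaded resonance frequency, Hz.
#' @param f_res loaded resonance frequency, Hz (`0 < f_res <= f0`).
#' @param m0 string mass, ng.
#' @return Sample mass in the same units as `m0` (>= 0, zero when
#'   `f_res == f0`, increasing as `f_res` falls).
#' @examples
#' estimate_sample_mass(f0 = 200e3, f_res = 190e3, m0 = 10)
#' @export
estimate_sample_mass <- function(f0, f_res, m0) {
  stopifnot_scalar(f0, "f0"); stopifnot_scalar(f_res, "f_res")
  stopifnot_scalar(m0, "m0")
  if (f_res <= 0) stop("f_res must be positive")
  if (f_res > f0) stop("f_res > f0 would imply a negative sample mass")
  if (m0 <= 0) stop("m0 must be positive")
  pi * m0 * (f0^2 - f_res^2) / ((pi + 2) * f_res^2)
}
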