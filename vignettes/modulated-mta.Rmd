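---
title: "Temperature-modulated micromechanical thermal analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temperature-modulated micromechanical thermal analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mta)
```

## The measurement this package models

Micromechanical thermal analysis (MTA) deposits pico- to nanogram amounts of
sample on resonating silicon-rich nitride microstrings and tracks each
string's resonance frequency and quality factor during a heating ramp in a
vacuum chamber. Heating relaxes the tensile stress between string and frame,
so frequency falls roughly linearly with temperature; thermal events of the
sample superimpose on that baseline. In the temperature-modulated variant a
sinusoid rides on the linear ramp (as in modulated DSC), realized by
pulse-width modulation of a Peltier element:

$$DC(t) = k_s + k_l t + A_{mod}\sin(2\pi t/P), \qquad
  T(t) = T_0 + \tfrac{\text{rate}}{60}\,t + a_T \sin(2\pi t/P).$$

The simulator works directly in temperature space (`T0`, `rate`, `amp_T`)
and keeps the duty-cycle law (`duty_cycle()`) for fidelity; the
duty-to-temperature map is taken as linear because only the achieved
temperature settings, not the heater calibration, are knowable from the
measurement side. Defaults follow the instrument settings the package
emulates: 30--70 °C at 1.6 °C/min, ±0.2 °C modulation with a 20 s period,
0.2 s sampling, and a 163 kHz fundamental.

## Signal model

`simulate_measurement()` builds, per tracked mode $n$,

$$f_n(t) = f_{n,\mathrm{loaded}} + c_T\,(T(t)-T_0)
          + r_n\,\Delta f(T(t)) + \varepsilon,$$

with $c_T = -30$ Hz/°C by default (frequency falls on heating; the
magnitude is a plausible mid-range choice, the sign is physical), per-mode
responsivity multipliers $r_n$, and i.i.d. Gaussian noise (sd 0.5 Hz).
Because each mode responds to the *instantaneous* modulated temperature,
the applied period transfers to the frequency trace with local slope
$|c_T + \Delta f'(T)|$ — exactly the mechanism the reversing signal
exploits.

The glass-transition detuning $\Delta f(T)$ is a logistic step of total
depth `detune_total` (default 300 Hz, chosen to stand clearly above the
0.5 Hz noise) centered at the static onset `tg_static` (45 °C); with
`two_step = TRUE` the depth is split between logistics at `tg_static` and
`tg_dynamic` (50 °C), emulating the two-fold frequency change that
accompanies large effective-mass redistributions. The step width defaults
to 0.5 °C: the observations this scenario emulates place the initial UFS
slope change and the reversing-signal maximum at the same temperature on a
1 °C reporting scale, which requires the step to be sharp (a logistic's
visible onset leads its center by roughly two to three widths). This
sharpness choice is a property of the emulated material response, not of
the detectors.

The quality factor follows a dip-then-rise curve: a Gaussian dip (depth
400) centered at `tg_dynamic`, and a sharp rise (height 600, width
`step_width/2`) centered at `tg_dynamic + 2*step_width`. Centering the dip
at `tg_dynamic` makes the noise-free minimum of the combined curve sit at
the embedded ground truth to within a few hundredths of a degree; placing
the rise partly on top of the dip instead (both centered at 50 °C) would
cancel the dip almost entirely and shift the minimum a degree early, which
contradicts the dip-then-sharp-rise morphology the scenario reproduces.
Baseline Q is 2000 with noise sd 8; all Q shape parameters are plausible
mid-vacuum values rather than measured constants.

## Mass loading and mode shapes

An unloaded string has the exact harmonic ladder $f_n = n f_1$. Deposited
mass detunes a mode through its effective load: each point particle is
weighted by $2\sin^2(n\pi x)$ — local mass responsivity scales with the
square of the local vibrational amplitude, and the factor 2 normalizes a
uniformly spread load to its full mass. The frequency-load relation is
defined as the exact inverse of the distributed-load mass approximation

$$m_{\mathrm{sample}} = \frac{\pi m_0 (f_0^2 - f_{res}^2)}{(\pi+2) f_{res}^2},$$

so `estimate_sample_mass()` round-trips `loaded_mode_frequency()` to
machine precision for a reference distributed load — making the mass
pipeline exactly testable. The string mass default (23 ng) follows from
nominal geometry (800 µm × 50 µm × 193 nm SiRN at ~3 g/cm³).

`classify_mode()` labels grid-overlay vibrometer measurements (23×3 = 69
points by default; a 7×3 = 21-point low-resolution variant also works for
$n \le 3$): amplitudes are rotated to the global phase maximizing their
real energy (making the label invariant to phase and scale), the harmonic
is one plus the sign changes of the width-averaged profile (near-node
samples below 5% of the profile maximum are ignored), and a mode is
"mixed" when the outer width rows differ by more than `mixedness = 0.3`
of the grid maximum — a threshold standing in for the visual judgement
used in practice. `detect_mode_switches()` debounces prominent-mode label
flicker with `debounce_n = 3` samples.

## Deconvolution

`deconvolve()` chains the stages:

1. **Underlying signal (UFS).** First-order Savitzky–Golay filter with a
   frame length of one modulation period (nearest odd sample count; the
   filter's polynomial edge fits keep the output full length). The filter
   preserves straight lines exactly and attenuates the period-$P$ sinusoid
   below 2% at the default settings.
2. **Periodic part.** `raw - UFS`, so the reconstruction identity
   `ufs + periodic == raw` holds to machine precision.
3. **Upper envelopes.** Magnitude of the Fourier-domain analytic signal
   (Hilbert construction), smoothed with the same one-period filter. The
   first and last full period carry edge artifacts and are flagged; all
   detectors ignore them.
4. **Reversing signal.** $RS = P_{ue} / (TS_{ue}\, P / 2\pi)$, the
   envelope of the periodic frequency response normalized by the envelope
   of the temperature modulation. For a linear response with slope $c$,
   $RS \equiv |c|\,2\pi/P$ (the default scenario gives $3\pi$); transient
   responses appear as local maxima. RS is reported in the units this
   ratio produces, since it is used for peak localization only.

`dominant_frequency()` verifies the modulation transfer. The trace is
detrended by first differencing rather than by removing a fitted line: a
trace containing a glass-transition step leaks far more magnitude into the
lowest FFT bins than the modulation peak carries (measured: roughly 4000
vs 460 normalized units on the default scenario), so a linear detrend
would report the trend residual; differencing suppresses low-frequency
content in proportion to frequency while leaving the periodic component in
exactly the same bin.

## Transition detection

* **Tg_F** — first local maximum of the reversing signal passing the
  prominence rule: prominence at least `prominence_frac = 0.2` of
  `max(rs) - median(rs)` *and* above a noise floor of 20 robust standard
  deviations of the sub-period RS residual. The floor matters: white
  measurement noise passed through the envelope/smoothing chain produces
  period-scale bumps whose prominence is an essentially fixed multiple
  (~12×) of that residual scale, and without the floor a weakly detuned
  trace reports those bumps as transitions.
* **Tg_Q** — most prominent local minimum of the one-period-smoothed
  quality factor; when no minimum is pronounced (the quality factor does
  not always dip, but always shifts upward at the transition) the detector
  falls back to the intersection of the pre-rise baseline tangent with the
  maximum-slope tangent. For a pure logistic rise of width $w$ this
  construction lands $2w$ before the rise midpoint, within half the
  10–90% width.
* **UFS onset and Δf** — a continuous two-segment piecewise-linear least
  squares fit, scanned over candidate breakpoints in the central 80% of an
  analysis window (ties toward lower temperature). The window runs from
  the start of the trace to the first approach (95%) of the maximum
  deviation from a provisional pre-transition baseline: a transition that
  completes and then runs parallel to the old baseline would otherwise
  pull the globally optimal breakpoint several degrees past the slope
  change. If the two-segment fit fails to reduce the residual sum of
  squares by `min_improvement = 0.25` over a single line, no onset is
  reported — the trace shows no pronounced detuning. Δf is the maximum
  deviation of the UFS from the pre-transition line refitted up to the
  onset (with a 10% margin so the step's leading tail does not bias the
  extrapolation). Note that on a logistic step any onset construction
  dates the transition one to two widths before the step center; the
  detector therefore reports the leading edge, about 1.5 °C below the
  embedded 45 °C center at the default width.

## Image stack simulation and analysis

`render_frames()` draws anti-aliased disks on 8-bit frames (512×128 px at
1.5 px/µm by default, matching 50 µm strings at ~75 px width). Each
particle's projected area follows a shrink-then-spread law in the
lag-shifted temperature $\tau = T - T_g^{dyn} - \text{lag}\cdot d$: a 5%
area loss with its minimum exactly at $\tau = 0$, then a rise to +60%,
with `lag_per_um = 0.2` °C/µm so larger particles bottom out later (all
three magnitudes are plausible choices; the measurements they emulate
report the ordering, not the magnitudes). Radii scale as the square root
of the area factor since only the 2-D projection is modeled.

`contour_levels()` segments at a threshold fixed from the first frame
(background plus half the median foreground contrast), fills holes, labels
connected components, and bins them by equivalent diameter
$2\sqrt{A/\pi}/\text{scale}$ into half-open classes [0, 5), [5, 10),
[10, ∞) µm. `track_levels()` counts member pixels per class and frame and
smooths each series with the one-period filter (falling back to a
five-frame window when frames are sampled more coarsely than $P/5$);
`area_minima()` reports each class's interior global minimum, absent for
monotone series. Two quantization caveats are deliberate: a particle whose
shrink excursion is sub-pixel can show a flat thresholded count (the
default particle sizes avoid class-edge crossings for this reason), and
minima of quantized counts form plateaus, so minimum temperatures are
meaningful to about one frame spacing.

## Scenario bundles

`make_scenario()` returns deterministic, seedable end-to-end fixtures:
the default and two-step indomethacin scenarios; two sub-nanogram loadings
whose distributed loads are back-solved so the mass approximation returns
exactly 433 pg and 494 pg; a heavy-loading scenario; a heavy-loading
scenario with an injected prominent-mode switch; and a four-mode
single-string scenario in which the two mixed (torsionally involved)
modes carry responsivities 1.0 and 0.8 against 0.3 and 0.25 for the
flexural modes, so their detuning derivative extrema are strictly larger.
All randomness is deferred to seeded generators, so identical
`(name, seed)` pairs rebuild bit-identical bundles.

## What the simulations do and do not show

The generator reproduces the *structure* of modulated-MTA measurements:
modulation transfer, a dual transition signature with the quality-factor
transition 5 °C above the reversing-signal onset, detuning magnitudes from
sub-noise to kilohertz, and size-ordered image-area minima. It does not
model thermal-lag physics (the image lag is phenomenological), viscosity
or relaxation-time distributions, vacuum-pressure effects, non-Gaussian
read-out noise, or mode-coupling mechanics, and real traces contain drift
and mode-crossing artifacts the simulator omits. Passing tests therefore
demonstrate that the analysis chain recovers known ground truth under
realistic noise — not that it is validated on instrument data.

Problem sizes used throughout (7501-sample traces, ~100–150-frame stacks,
12-replicate recovery studies) were chosen as the smallest that leave the
detectors' asymptotics visible.
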