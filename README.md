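# mta — temperature-modulated micromechanical thermal analysis

Micromechanical thermal analysis (MTA) tracks the resonance frequency and
quality factor of sample-loaded silicon-rich nitride microstrings during a
heating ramp, characterizing pico- to nanogram amounts of material — far
below what differential scanning calorimetry needs. Superimposing a
sinusoidal modulation on the ramp (as in modulated DSC) and deconvolving
the response separates the slowly varying **underlying frequency signal
(UFS)** from the **reversing signal (RS)**,

    RS(t) = P_ue(t) / ( TS_ue(t) · P / 2π ),

the envelope of the periodic frequency response normalized by the envelope
of the applied temperature modulation. The RS localizes transient thermal
responses: its first prominent maximum marks the static glass-transition
onset **Tg_F**, while the quality-factor minimum (or rise onset) marks the
dynamic, liquefaction-side transition **Tg_Q**, typically a few degrees
higher. The package is aimed at people developing or analyzing
resonator-based thermal analysis: it provides the full computational
pipeline plus simulators for every input, so everything runs without an
instrument.

What is implemented:

* **Signal simulation** — modulated heating programs, string-resonator
  physics (exact harmonic ladder, mode-shape-weighted mass loading), and
  glass-transition scenarios with embedded ground truth
  (`temperature_program()`, `string_model()`, `tg_scenario()`,
  `simulate_measurement()`, `make_scenario()`).
* **Deconvolution** — one-period first-order Savitzky–Golay UFS, Hilbert
  upper envelopes, reversing signal, FFT modulation check
  (`deconvolve()`, `dominant_frequency()`).
* **Transition detection** — RS maxima, quality-factor transition, UFS
  onset and maximum detuning Δf, assembled by `build_report()`.
* **Sample mass estimation** from resonance detuning,
  `estimate_sample_mass()`: m = π·m0·(f0² − f²) / ((π+2)·f²).
* **Image analysis** — synthetic 8-bit frame stacks of particles that
  shrink then spread through the transition, and three-level
  (<5 µm / 5–10 µm / >10 µm) contour area tracking
  (`render_frames()`, `track_levels()`, `area_minima()`).
* **Mode-shape analysis** — flexural/mixed classification of grid-overlay
  vibrometer measurements, prominent-mode identification and switch
  detection (`classify_mode()`, `prominent_mode()`,
  `detect_mode_switches()`).

## Worked example

```r
library(mta)

b <- make_scenario("indomethacin_default", seed = 1)
m <- simulate_bundle(b)          # 30-70 degC, 1.6 C/min, +/-0.2 degC / 20 s
d <- deconvolve(m)
report <- build_report(d, m$quality[[1]])
report
#> Glass-transition report (mode mode1 )
#>   Tg_F (reversing signal): 45.16 degC
#>   Tg_Q (minimum):               50.01 degC
#>   Tg_Q - Tg_F:             4.85 degC
#>   UFS onset:               43.52 degC
#>   max detuning:            305.8 Hz

dominant_frequency(m$freq[[1]], m$dt)
#> [1] 0.05
```

The scenario embeds a static onset at 45 °C and a liquefaction transition
at 50 °C with a 300 Hz detuning step. The report recovers both: the first
reversing-signal maximum lands at 45.2 °C (Tg_F), the quality-factor
minimum at 50.0 °C (Tg_Q), their difference ~4.9 °C, and the measured
maximum detuning ~306 Hz. The UFS onset sits ~1.5 °C before the step
center — an onset construction dates the leading edge of the transition.
The 0.05 Hz spectral maximum confirms the direct transfer of the 20 s
modulation period into the resonance-frequency response.

Mass estimation round-trips the forward load model exactly:

```r
s <- string_model()                                   # 163 kHz, 23 ng
f <- loaded_mode_frequency(s, distributed_mass = 0.433)
estimate_sample_mass(s$f1, f, s$m0)
#> [1] 0.433
```

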