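---
title: "Methods: layered-medium optoacoustic depth profiling and IRF deconvolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: layered-medium optoacoustic depth profiling and IRF deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oadepth)
```

## The measurement model

A nanosecond laser pulse illuminates a sample through a transparent
piezoelectric probe: a thin PVDF film glued between a thick PMMA *backing*
(which delays rear reflections) and a thin PMMA *fronting* (which protects
the film and fixes the detector–sample distance). Light absorbed at optical
absorption coefficient $\mu_a$ under fluence $F$ deposits energy that
converts to an initial pressure

$$p_0(z) \;=\; \Gamma(z)\, \mu_a(z)\, F\, e^{-\int_0^z \mu_a\,dz'},$$

with $\Gamma$ the Grüneisen coefficient. In the acoustic near field the
pressure transient reaching the detector is the 1D propagated image of
$p_0$, so arrival time maps to depth through the sound velocity. The
recorded voltage, however, is that pressure convolved with the system's
instrument response function (IRF) — the film's finite thickness, electrode
resistance and amplifier all act as a low-pass — and overlaid with a slow
pyroelectric voltage from light absorbed in the film itself.

The package implements the three layers of this model:

1. **Stack acoustics.** Layers are ordered from the detector-side backing
   toward the sample; boundaries are indexed $0..N$ around the $N$ layers.
   Pressure coefficients at a boundary from impedance $Z_1$ into $Z_2$ are
   $R = (Z_2 - Z_1)/(Z_2 + Z_1)$ and $T = 1 + R$; the pressure convention is
   used throughout because the film transduces pressure. Air outside the
   stack is the pressure-release limit $Z \to 0$ ($R = -1$), a rigid mount
   the limit $Z \to \infty$ ($R = +1$); both are sentinels rather than
   layers, so no fictitious air parameters enter the model.
   `enumerate_echoes()` traces every reflection itinerary up to a reflection
   count and amplitude floor and is the package's arrival-time oracle. Note
   that pressure transmission exceeds unity into stiffer media; only the
   per-boundary $|R| \le 1$ is a hard bound, while any round trip attenuates
   ($T_{12} T_{21} \le 1$).

2. **Forward simulation.** `fd_simulate()` integrates the first-order
   system $\partial_t p = -\rho c^2 \partial_z v$,
   $\partial_t v = -\rho^{-1}\partial_z p$ with a staggered-grid leapfrog:
   pressure at cell centers, velocity on faces at half time steps. The
   scheme handles piecewise-constant impedance without interface fitting,
   which is why a layer split into two identical halves is *bit-identical*
   to the unsplit medium. Initial conditions are $p = p_0$, $v = 0$; the
   pulse splits into two half-amplitude counter-propagating waves, the
   physically correct photoacoustic start.

3. **Signal chain.** `remove_pyroelectric_baseline()` projects out a
   polynomial fitted on samples outside a *signal mask*;
   `extract_irf()` windows the baseline-removed quasi-delta measurement
   with a Butterworth time window, zero elsewhere; `deconvolve()` divides
   spectra, applies the zero-phase Butterworth low-pass and
   back-transforms.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| baseline polynomial order | 10 | — | absorbs any smooth valley while leaving ~100 ns pulses intact |
| time-window order / low-pass order | 4 | — | steep enough to suppress neighbours/noise, gentle enough to avoid ringing; the method itself fixes no order |
| low-pass cutoff | 20 | MHz | the band above which deconvolved output is noise-dominated for this probe class; raising it a few MHz destabilizes the division |
| spectral floor `epsilon` | 10⁻³ | of max \|FFT(irf)\| | clamps near-zero denominator bins; magnitude-only, phase kept |
| echo `amplitude_floor` | 10⁻³ | — | keeps echo lists finite; configurable |
| grid `dx` | thinnest layer / 4 | m | resolves the 10 µm film; `dt = 0.9·dx/max(c)` satisfies CFL |
| Grüneisen $\Gamma$ | 1 per layer | — | never measured here; every comparison is shape/timing-based, so the absolute pressure scale is arbitrary |
| fluence | 50 | J/m² | typical frequency-doubled Nd:YAG exposure for this probe |
| trigger delay | 1.12 | µs | laser fires 1.12 µs after the DAQ trigger; arrivals are `trigger_delay + time of flight` |

Time axis convention: $t = 0$ at the DAQ trigger, the laser fires at
`trigger_delay`. This is the axis on which the bench numbers read naturally
(primary arrival = 1.12 µs + fronting transit ≈ 1.31 µs; backing–air echo
3.62 µs later).

## Numerical choices

- **Polynomial conditioning.** The baseline fit rescales time to
  $[-1, 1]$ and uses an orthogonal polynomial basis — an identical
  projection to raw monomials, but well conditioned at order 10. The
  operation is idempotent by construction.
- **Zero-phase filtering.** The frequency-domain Butterworth is applied as
  a real magnitude mask on the two-sided spectrum. A causal IIR filter
  would delay and skew peaks; the magnitude mask preserves peak timing
  exactly, which is what arrival-time comparisons need. The time-domain
  Butterworth is likewise applied as a *window* (multiplication), matching
  its role of cutting reflections out of the IRF without sharp edges.
- **Deconvolution alignment.** Spectral division cancels the kernel's
  position inside its own trace, so lag 0 corresponds to the IRF's
  reference arrival. `align = "irf"` restores absolute trace time;
  `align = "first_peak"` applies the set-the-first-peak-to-zero convention
  used when overlaying a deconvolved measurement on a simulation.
- **Energy bookkeeping.** The solver's conserved quantity is the discrete
  leapfrog invariant (kinetic term at half steps, potential term as the
  product of bracketing pressure fields, quarter-cell weights on the outer
  faces). With reflective outer faces it is conserved to machine precision;
  the packaged test asserts < 0.1 % over a multi-microsecond window.
- **Degenerate inputs.** Zero-thickness layers are legal and contribute no
  time of flight; an all-zero source, CFL violations, masks that exhaust
  the baseline fit, windows that do not overlap the trace, cutoffs at or
  above Nyquist, and all-zero IRFs raise informative errors.

## What the synthetic generator does and does not emulate

`synth_raw_trace()` produces
`(simulated pressure delayed by the trigger) ⊛ kernel + valley + noise`
and returns each component, so every processing stage has exact ground
truth. Defaults, chosen once as a realistic bench configuration: 250 MS/s
acquisition (fast enough that Nyquist, 125 MHz, dwarfs the 20 MHz band;
far below the hardware's 8 GS/s so tests stay quick), 20 MHz kernel
bandwidth matching the processing band, a 0.2 V pyroelectric valley
(the thermal background is of the same order as the acoustic signal),
2 mV additive noise, and a 10⁻⁷ V/Pa detector gain (arbitrary scale).

The pyroelectric valley is a difference of exponentials with 4 µs decay and
2 µs rise. The physical drift's details depend on uncontrolled factors
(e.g. sample capacitance) and are treated as unknown; what matters for
fidelity is that the stand-in is a broad smooth valley that a 10th-order
polynomial can absorb — the packaged drift is absorbed to 1.4 % RMS of its
depth. Sharper valley onsets (sub-µs rise) violate that absorbability and
would misrepresent the method's own working assumption.

Not emulated: electromagnetic pickup and grounding artifacts, the
dependence of the valley shape on sample capacitance, frequency-dependent
acoustic attenuation, finite laser pulse duration (8 ns, far below every
processing time scale and subsumed by the kernel), and all multi-dimensional
effects. Passing the end-to-end tests therefore demonstrates the signal
chain's correctness under its stated 1D near-field assumptions, not
robustness to the full mess of a clinical measurement.

## Open design decisions taken here

- The time-domain Butterworth is a window, not a causal filter: the
  published processing figure shows a window-like envelope, and windowing
  is the only reading under which "zero-padding outside the window"
  is meaningful.
- The fronting transit computed from the tabulated layer parameters is
  0.190 µs, while the measured bench value is 0.21 µs (the tabulated
  adhesive properties are estimates). The package computes from the layer
  table and treats the ~0.02 µs gap as input uncertainty rather than
  choosing a side.
- The scan-map amplitude metric is the peak absolute sample of the
  transient (`peak_to_peak` available): the simplest definition consistent
  with "amplitude of the pyroelectric signal".
- Energy calibration is a proportional fit through the origin: zero light
  gives zero diode voltage.

## Problem sizes

The test suite and acceptance script run the solver at the default grid for
the probe stacks (≈ 2.5 µm cells, ~2900 cells, ~5000–6000 steps, a few
seconds per run) and keep property sweeps at hundreds-to-thousands of
samples — sizes chosen so the whole suite completes in well under a minute
while every grid still resolves the thinnest layer by at least four cells.

## Known limitations

- 1D only: no diffraction, oblique incidence or shear conversion; valid in
  the near field and increasingly wrong at long run times.
- No acoustic attenuation or dispersion: echo amplitudes at late times are
  upper bounds.
- Spectral division is the method's deconvolution; no Wiener or iterative
  schemes are provided.
- The exact cutoff above which the deconvolution destabilizes is
  setup-dependent; the package exposes the cutoff but does not estimate it.
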