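# oadepth

Optoacoustic (photoacoustic) depth profiling with a thin piezoelectric film
detector embedded in a layered probe.

A short laser pulse absorbed in a sample launches a pressure transient whose
time profile encodes the depth-resolved absorbed-energy distribution: an
A-scan. When the detector sits in the acoustic near field, the 1D pressure
profile arrives undistorted by diffraction, but it is still blurred by the
measurement chain — detector film thickness, electrode resistance, amplifier —
and overlaid by a slow pyroelectric voltage from light absorbed in the film
itself. `oadepth` implements the complete recovery chain for such probes,
aimed at anyone building or simulating layered-probe optoacoustic sensors:

- **Layer-stack acoustics** — impedance `Z = ρc`, pressure reflection
  `R = (Z₂ − Z₁)/(Z₂ + Z₁)` and transmission `T = 2Z₂/(Z₁ + Z₂)`
  coefficients, times of flight, and exhaustive echo-path enumeration that
  predicts every arrival time a layered probe produces.
- **1D forward simulation** — a staggered-grid leapfrog solver for the
  first-order acoustic system (`∂p/∂t = −ρc² ∂v/∂z`, `∂v/∂t = −ρ⁻¹ ∂p/∂z`)
  with a Beer–Lambert initial pressure `p₀(z) = Γ μₐ F e^{−∫μₐ}`, piecewise
  material properties, and pressure-release / rigid / absorbing outer faces.
- **Signal processing** — pyroelectric baseline removal by masked 10th-order
  polynomial fit; instrument-response-function (IRF) isolation with a
  Butterworth *time window* `W(t) = (1 + ((t−t₀)/τ)^{2n})^{−1/2}`;
  a zero-phase frequency-domain Butterworth low-pass
  `|H(f)| = (1 + (f/f_c)^{2n})^{−1/2}` (default cutoff 20 MHz); and FFT
  deconvolution `p = F⁻¹[ H · F(s) / F(k) ]` with a floored denominator.
- **Pyroelectric scan maps** — energy-normalized active-area maps from
  repeated transients on a lateral position grid, plus photodiode-to-energy
  calibration.
- **Synthetic data** — a seeded generator (simulated pressure ⊛ band-limited
  kernel + smooth pyroelectric valley + Gaussian noise) that returns exact
  ground truth for every pipeline stage.

## Worked example

A full synthetic measurement on the probe pressed against a strongly
absorbing sample, processed end to end:

```r
library(oadepth)

stack <- read_stack(system.file("extdata", "black_plastic.yaml",
                                package = "oadepth"))
spec <- synth_spec(stack, seed = 7)       # 250 MS/s, 1.12 us trigger delay
syn  <- synth_raw_trace(spec)

mask <- propose_signal_mask(stack, source_boundary = 5,
                            trigger_delay = spec$trigger_delay,
                            half_width = 0.12e-6, max_reflections = 2,
                            amplitude_floor = 5e-3)
clean <- remove_pyroelectric_baseline(syn$trace, mask)
irf   <- extract_irf(syn$trace, mask, half_width = 0.25e-6)
dec   <- deconvolve(clean, irf, cutoff = 20e6, align = "irf")

tt  <- trace_times(dec)
sel <- tt >= mask$start[1] & tt < mask$end[1]
```

Printing the intermediate objects:

```
<oa_trace> 1501 samples @ 4 ns, t0 = 0 us, span = 6 us [V]
  trigger_delay = 1.12 us
  amplitude range [-0.4504, 0.1956]
<oa_irf> kernel of 1501 samples @ 4 ns
  reference arrival 1.316 us; window center 1.316 us, half-width 0.25 us (order 4)
recovered primary arrival: 1.3160 us (ground truth 1.3134 us)
```

The raw trace's dominant feature is the −0.45 V pyroelectric valley; after
baseline removal, windowed IRF extraction and deconvolution, the primary
acoustic arrival is recovered within one 4 ns sample of the generator's
ground truth (the trigger delay of 1.12 µs plus the ~0.19 µs transit of the
fronting stack).

The closed-form resolution bookkeeping for the 20 MHz processing band:

```r
resolution_limits(cutoff = 20e6, sound_velocity = 2150,
                  detector_thickness = 10e-6)
# min duration 50 ns, min depth 0.1075 mm, mu_a limits 9.3 / 100 per mm
```

i.e. a 20 MHz band admits no feature shorter than 50 ns ≈ 0.11 mm of travel
at 2150 m/s, so absorbers weaker than ~10 mm⁻¹ cannot act as delta sources,
while the 10 µm detector film alone would allow up to ~100 mm⁻¹.

## Layer configuration format

Stacks are YAML files, ordered from the detector-side backing toward the
sample (see `inst/extdata/`):

```yaml
layers:
  - material: PMMA
    sound_velocity_m_s: 2777
    thickness_mm: 5.00
    density_kg_m3: 1000
    mu_a_per_mm: 0
  # ...
detector: PVDF
boundaries: [air, air]
```
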