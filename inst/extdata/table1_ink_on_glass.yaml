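# Probe + ink-on-glass test sample, ordered from the detector-side backing
# toward the sample. Densities are all 1000 kg/m3 (the simulation treats the
# stack as unit-density); adhesive sound velocity/thickness and ink
# properties are estimated values. mu_a: only the ink layer absorbs; its
# coefficient (100 /mm) is of the order of a strongly absorbing marker ink
# (too high to measure precisely).
layers:
  - material: PMMA        # backing
    sound_velocity_m_s: 2777
    thickness_mm: 5.00
    density_kg_m3: 1000
    mu_a_per_mm: 0
  - material: Adhesive    # estimated
    sound_velocity_m_s: 2000
    thickness_mm: 0.02
    density_kg_m3: 1000
    mu_a_per_mm: 0
  - material: PVDF        # datasheet velocity
    sound_velocity_m_s: 2250
    thickness_mm: 0.01
    density_kg_m3: 1000
    mu_a_per_mm: 0
  - material: Adhesive    # estimated
    sound_velocity_m_s: 2000
    thickness_mm: 0.02
    density_kg_m3: 1000
    mu_a_per_mm: 0
  - material: PMMA        # fronting
    sound_velocity_m_s: 2777
    thickness_mm: 0.5
    density_kg_m3: 1000
    mu_a_per_mm: 0
  - material: Ink         # estimated
    sound_velocity_m_s: 1500
    thickness_mm: 0.04
    density_kg_m3: 1000
    mu_a_per_mm: 100
  - material: Glass
    sound_velocity_m_s: 5640
    thickness_mm: 4.00
    density_kg_m3: 1000
    mu_a_per_mm: 0
detector: PVDF
boundaries: [air, air]
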