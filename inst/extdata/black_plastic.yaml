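# Probe on a 1.65 mm thick piece of strongly absorbing black plastic
# (c = 2150 m/s), the quasi-delta source used to measure the instrument
# response function. mu_a 100 /mm is the order of magnitude consistent with
# the film-thickness resolution bound; the true value is too high to
# measure.
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
  - material: BlackPlastic
    sound_velocity_m_s: 2150
    thickness_mm: 1.65
    density_kg_m3: 1000
    mu_a_per_mm: 100
detector: PVDF
boundaries: [air, air]
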