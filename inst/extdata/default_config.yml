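years: 30
spinup_years: 10
closure_month: ~
F_mult:
  anchovy: 1.0
  sardine: 1.0
init_buffer_batches: 30.0
species:
  anchovy:
    n_adult_classes: 3
    length_windows:
    - 4.0
    - 11.0
    - 42.0
    - 100.0
    L_m: 100.0
    lw:
      b0: -6.1158
      b1: 3.5764
      b2: -0.616
      d1: 1.5798
      b3: 0.7137
      d2: 1.954
    T_opt:
    - 17.25
    - 16.25
    - 15.800000000000001
    - 15.800000000000001
    Q_c:
    - 2.22
    - 2.22
    - 2.4
    - 2.4
    T_max: 27.0
    k_half:
      early: 0.864
      late:
      - 0.25
      - 0.2
      juvenile: 0.45
      adult:
      - 1.2
      - 1.4
      - 1.3
    DSF: 46.0
    egg_energy: 0.66
    E_egg: 0.012
    sst_gate: above
    sst_threshold: 15.0
    M:
    - 0.4
    - 0.2
    - 0.05
    - 0.012
    - 0.002
    F_adult: 0.00136
    ref_biomass: 40000.0
    init_lengths:
    - 120.0
    - 135.0
    - 145.0
    k_alloc: 0.5
    atresia_days: 9
    CAL_z: 2580.0
    CAL_f: 5400.0
    a_c: 0.41
    b_c: -0.31
    a_f:
    - 0.15
    - 0.15
    - 0.126
    - 0.126
    a_e: 0.41
    b_e: 0.01
    a_sda: 0.1
    resp:
      a_r: 0.003
      b_r: -0.34
      Q10: 1.3
      T_m: 16.0
      d_r: 0.022
      a_A_cold: 2.0
      c_A_cold: 0.149
      c_A_warm: 0.0
      a_A_warm:
      - 12.25
      - 12.25
      - 11.98
      - 14.210000000000001
      a_A_lowfeed: 9.970000000000001
      b_A:
      - 0.27
      - 0.27
      - 0.33
      - 0.27
  sardine:
    n_adult_classes: 4
    length_windows:
    - 5.0
    - 13.0
    - 50.0
    - 105.0
    L_m: 105.0
    lw:
      b0: -9.228999999999999
      b1: 5.391
      b2: -2.281
      d1: 1.699
      b3: 0.106
      d2: 2.02
    T_opt:
    - 14.5
    - 14.75
    - 15.800000000000001
    - 15.800000000000001
    Q_c:
    - 2.22
    - 2.22
    - 2.4
    - 2.4
    T_max: 27.0
    k_half:
      early: 0.6
      late:
      - 0.3
      - 0.15
      juvenile: 1.05
      adult:
      - 1.6
      - 1.3
      - 1.3
      - 1.3
    DSF: 20.100000000000001
    egg_energy: 1.11
    E_egg: 0.0086
    sst_gate: below
    sst_threshold: 16.0
    M:
    - 0.4
    - 0.2
    - 0.05
    - 0.012
    - 0.002
    F_adult: 0.002
    ref_biomass: 25000.0
    init_lengths:
    - 130.0
    - 150.0
    - 165.0
    - 175.0
    k_alloc: 0.5
    atresia_days: 9
    CAL_z: 2580.0
    CAL_f: 5400.0
    a_c: 0.41
    b_c: -0.31
    a_f:
    - 0.15
    - 0.15
    - 0.126
    - 0.126
    a_e: 0.41
    b_e: 0.01
    a_sda: 0.1
    resp:
      a_r: 0.003
      b_r: -0.34
      Q10: 1.3
      T_m: 16.0
      d_r: 0.022
      a_A_cold: 2.0
      c_A_cold: 0.149
      c_A_warm: 0.0
      a_A_warm:
      - 12.25
      - 12.25
      - 11.98
      - 14.210000000000001
      a_A_lowfeed: 9.970000000000001
      b_A:
      - 0.27
      - 0.27
      - 0.33
      - 0.27
forcing:
  sst_anchors:
  - 13.800000000000001
  - 13.199999999999999
  - 13.800000000000001
  - 15.0
  - 18.5
  - 22.5
  - 25.0
  - 25.5
  - 23.5
  - 19.5
  - 15.800000000000001
  - 14.300000000000001
  T_deep: 14.5
  z_thermo: 30.0
  thermo_width: 4.0
  meso_low: 8.0
  meso_peak: 45.0
  meso_rise_start: 350.0
  meso_peak_day: 165.0
  meso_crash_end: 230.0
  micro_low: 18.0
  micro_peak: 35.0
  micro_rise_start: 330.0
  micro_peak_day: 130.0
  micro_crash_end: 250.0
  deep_max_depth: 40.0
  deep_max_width: 15.0
  surface_scale: 40.0
  micro_surface_scale: 30.0
  relax_rate: 0.1
  grazing_feedback: yes
  habitat_area: 50000000000.0
  carbon_to_wet: 12.5
  n_bins: 10
  max_depth: 100.0
  day_fraction: 0.5
  lowfeed_frac: 0.5
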