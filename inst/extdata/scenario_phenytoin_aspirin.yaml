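drug_toxic:
  name: phenytoin
  mw: 252.27000000000001
  site: SudlowI
  K_A: 15553.500416165730712
  k_on: 100000000.0
  t_half_total: 2100.0
  therapeutic_range:
  - 10.0
  - 20.0
  lambda_free: .na.real
  calibration_peak: 70.0
initial_conc: 70.0
patient:
  V_pl: 3.5
  V_is: 14.0
  V_ic: 28.0
  hematocrit: 0.35
  albumin_plasma: 650.0
  albumin_interstitial: 260.0
  K_ip: 1200.0
  K_ic: 100.0
dialyzer:
  KoA_free: 800.0
  sigma_free: 0.0
  sigma_protein: 0.999
  membrane_area: 1.8
  fiber_inner_diameter: 0.02
  fiber_length: 23.0
  n_fibers: 12455.604241974417164
  area_lumen: 0.000314159265359
  area_dialysate: 0.000628318530718
tube:
  length: 150.0
  inner_diameter: 0.4
session:
  Q_blood: 250.0
  Q_dialysate: 500.0
  max_duration: 1440.0
  rebound_horizon: 720.0
infusion:
  drug:
    name: aspirin
    mw: 180.159999999999997
    site: SudlowI
    K_A: 190000.0
    k_on: 100000000.0
    t_half_total: 20.0
    therapeutic_range: ~
    lambda_free: .na.real
    calibration_peak: 20.0
  dose: 2000.0
  diluent_volume: 500.0
grid:
  n_tube: 16.0
  n_dz: 64.0
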