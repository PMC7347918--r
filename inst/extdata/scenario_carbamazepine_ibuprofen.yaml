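drug_toxic:
  name: carbamazepine
  mw: 236.27000000000001
  site: SudlowII
  K_A: 4902.697898329939562
  k_on: 100000000.0
  t_half_total: 1500.0
  therapeutic_range:
  - 4.0
  - 12.0
  lambda_free: .na.real
  calibration_peak: 35.0
initial_conc: 35.0
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
    name: ibuprofen
    mw: 206.280000000000001
    site: SudlowII
    K_A: 176000.0
    k_on: 100000000.0
    t_half_total: 120.0
    therapeutic_range: ~
    lambda_free: .na.real
    calibration_peak: 25.0
  dose: 800.0
  diluent_volume: 200.0
grid:
  n_tube: 16.0
  n_dz: 64.0
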