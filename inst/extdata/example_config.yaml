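# Example aneumt pipeline configuration (desk scale).
# Any key omitted here keeps the default_config() value; lengths in the
# geometry section are millimetres, everything else SI.
geometry:
  inlet_diameter_mm: 25.1
  max_diameter_mm: 50.2
  sac_length_mm: 75.3
  entrance_diameters: 2
  exit_diameters: 4
mesh:
  ni: 96
  nj: 28
  wall_stretch: 1
fluid:
  density: 1000
  dynamic_viscosity: 0.001
flow_bc:
  reynolds: 800          # or: flow_rate_m3s: 3.94e-6
flow:
  momentum_scheme: quick
  tol: 1.0e-3
species:
  schmidt: 100           # 3200 for the full dye Schmidt number
  dt: 1
  tol: 1.0e-3
schemes:
  names: [fou, power_law, sou, quick]
  quick_psi: 0.75
probe:
  extraction_volume_ml: 0.8
  n_slabs: 5
  schedule_s: [0, 120, 240, 360]
  withdrawal_s: 60
reference:
  type: pseudo_experiment
  tau: 240
  noise_sd: 0.02
  seed: 1
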