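output_dir: walker_out
walker:
  capture_radius_nm: 1.0
  kuhn_length_nm: 1.5
  ss_nm_per_nt: 0.63
  ds_nm_per_bp: 0.34
  arm_bound:
  - kind: duplex
    n_units: 6
    label: T2_stem
  - kind: duplex
    n_units: 34
    label: T2.F2.L2_stack
  - kind: single_stranded
    n_units: 3
    label: hinge
  - kind: single_stranded
    n_units: 15
    label: L1_free
  arm_fuel:
  - kind: duplex
    n_units: 24
    label: T1.F1_stack
  - kind: single_stranded
    n_units: 9
    label: F1_overhang
track:
  kind: flat
  radius_nm: 9.549296585513721
  walker_side: convex
kinetics:
  k_FB: 230000.0
  F1:
  - 1 nM
  - 10 nM
  - 100 nM
  - 1 uM
  - 10 uM
  d_ref_nm: 12.0
  k_s_ref: 3.0
  true_k_s:
    '5': 2.0
    '10': 4.0
    '15': 3.0
    '20': 2.0
    '25': 1.0
    '30': 0.02
    '35': 3.5e-05
    '40': 1.0e-07
    '45': 0.0
fret:
  E_LP: 0.2
  E_Trap: 0.8
  sd_LP: 0.1
  sd_Trap: 0.1
  n_bursts: 3000
  n_boot_ci: 100
sampling:
  n_conformations: 100000
  seed: 20211
  d_grid_nm:
  - 5.0
  - 10.0
  - 15.0
  - 20.0
  - 25.0
  - 30.0
  - 35.0
  - 40.0
  - 45.0
  bandwidth_nm: 1.0
  voxel_nm: 1.0
  n_boot: 30
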