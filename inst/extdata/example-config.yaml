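# Example run configuration: a hot, dry long day on a CAM-anatomy leaf.
environment:
  t_min: 28
  t_max: 38
  rh_min: 0.3
  rh_max: 0.7
  i_max: 800
  daylength: 14
  n_steps: 24
gas:
  ci_ratio: 0.7
constraints:
  co2_uptake_max: 15
  vacuole_capacity_c3: 0.03
scenario:
  icdh_mode: reversible
  vacuole_mode: CAM
  productivity_fraction: 80
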