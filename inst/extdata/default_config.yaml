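seed: 1.0
out_dir: '.'
acquisition:
  sample_rate: 100000.0
  v0: 1.0
  v_sat: 1.25
  noise_sd: 0.005
  channel_depth_um: 100.0
oil:
  phi: 0.35
  n_base: 1.29
  n_additive: 1.427
train:
  duration_s: 1.0
  frequency_hz: 1000.0
  n_aqueous: 1.337
  transit_fraction: 0.4
  shoulder_gain: 300.0
  empty_fraction: 0.0
  empty_dip: 0.02
  jitter_sd: 0.0
populations:
- label: tartrazine_0.5mM
  concentration_mm: 0.5
  volume_pl: 75.0
  proportion: 0.5
  epsilon: 38000.0
- label: tartrazine_5mM
  concentration_mm: 5.0
  volume_pl: 75.0
  proportion: 0.5
  epsilon: 38000.0
detector:
  baseline_alpha: 0.01
  enter_delta: 0.012
  shoulder_delta: 0.02
  exit_band: 0.01
  min_width: 0.0001
  max_width: 0.002
  debounce: 3.0
  smooth_n: 5.0
  init_time: 0.01
gate:
  a_low: 0.5
  a_high: 1.5
  min_width: 0.0001
  max_width: 0.002
  sort_empty: no
  mode: absorbance
pulse:
  delay: 0.0005
  width: 0.0001
  refractory: 0.0005
junction:
  force_scale: 1.3333333e-05
  volume_exponent: 1.0
  frequency_exponent: 1.0
  applied_force: 1.6
  margin: 0.2
  fragmentation_sharpness: 10.0
screen:
  ratio: 0.01
  n_droplets: 10000.0
  occupancy_lambda: 0.3
  n_clones: 38.0
  assay:
    pos_mean: 1.0
    pos_sd: 0.08
    neg_mean: 0.15
    neg_sd: 0.05
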