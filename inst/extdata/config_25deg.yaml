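schema_version: 1
photo:
  R: 1.0
  Cm: 20.0
  v_thresh: 0.0
  dt: 10.0
  mode: LT
lamina:
  R: 1.0
  Cm: 20.0
  v_thresh: 0.01
  dt: 10.0
  mode: LT
medulla:
  R: 2.0
  Cm: 5.0
  v_thresh: 0.01
  dt: 10.0
  mode: LT
directional:
  R: 1.0
  Cm: 10.0
  v_thresh: 0.0
  dt: 10.0
  mode: LT
chiasma:
  R: 1.0
  Cm: 10.0
  v_thresh: 0.01
  dt: 10.0
  mode: LT
lgmd:
  R: 1.0
  Cm: 15.0
  v_thresh: 0.15
  dt: 10.0
  mode: IAF
surround_weight: -0.125
onoff_delay: 1
delta_x: 5
delta_y: 5
coincidence_threshold: 0.02
coincidence_rule: min
trail_extent: 3
lateral_weight: 0.2
fan_sample_extent: 1
fanin_rule: opposite_pairs
fan_leak: 0.0
chiasma_threshold: 2
w_exc: 0.2
w_inh: 0.05
noise_sigma: 2.0
seed: 1
n_substeps: 4
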