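# Small demonstration profile: two coarse brain-like solids, a short
# growth run, morphometry, disk mapping and a similarity report.
output_dir: gyralkit_demo
seed: 1
stages: [synth, simulate, morphometry, map, compare]
synth:
  seeds: [1, 2]
  semi_axes: [1.0, 0.8, 0.7]
  n_modes: 3
  amplitude: 0.04
  target_edge: 0.45
simulate:
  g_g: 1.25
  g_w: 1.0
  mu_g: 1.0
  mu_w: 1.0
  bulk_ratio: 5
  h0: 0.2
  h_slope: 0.005
  protocol: continuous
  t_end: 1.0
  max_g_increment: 0.05
  max_iters: 600
landmarks:
  n_curves: 3
  min_separation: 0.15
morphometry:
  n_bins: 64
compare:
  p: [1, 2, inf]
  measures: [si, htilde]
  landmark_tol: 0.05
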