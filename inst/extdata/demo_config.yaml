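# One-command synthetic demo: generate a small two-group cohort with a
# planted gamma power effect and beta coupling, extract features, contrast
# the groups and cross-validate a linear SVM on the hybrid features.
seed: 7
out_dir: mpeeg_demo
synth:
  groups: {HC: 4, PD: 4}
  fs: 128
  duration_s: 30
  band_power_effects:
    PD:
      gamma: {channels: [Cz, C3, C4], factor: 2.0}
  plv_effects:
    PD:
      beta: {pairs: [[C3, C4], [F3, F4]], kappa: 50}
preprocess:
  band: [0.5, 50]
  epoch_length_s: 1.0
features:
  bands: [beta, gamma]
contrast:
  mode: PSD
  band: gamma
  groups: [PD, HC]
  alpha: 0.05
classify:
  mode: psd+plv
  band: gamma
  groups: [HC, PD]
  folds: 5
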