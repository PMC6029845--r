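# Desk-scale end-to-end run: simulate -> prep -> decode -> fuse -> stats ->
# report. See ?run_config for the full field reference.
seed: 42
synth:
  n_subjects: 4
  n_conditions: 8            # 4 faces + 4 objects
  n_trials_per_condition: 12
  n_channels: 16
  time_lim: [-100, 350]
  time_step: 10              # ms; native acquisition is 1 ms
  identity_envelope: {onset: 40, peak: 100, fwhm: 60, amplitude: 1.2}
  category_envelope: {onset: 110, peak: 170, fwhm: 80, amplitude: 1.5}
  noise_sd: 1
decoding:
  group_size: 3              # pseudo-trial averaging
  n_repetitions: 5           # 100 at production scale
  svm_cost: 1
  seed: 1
fusion:
  - {name: EVC, latency_ms: 100, n_voxels: 40, noise_sd: 0.1, n_subjects: 5}
  - {name: IT,  latency_ms: 170, n_voxels: 40, noise_sd: 0.1, n_subjects: 5}
stats:
  n_boot: 500                # 1000 at production scale
  n_perm: 500                # 1000 at production scale
  cdt: 0.05
  alpha: 0.05
  q: 0.05
behavior:
  dprime: {fast: 1.95, slow: 3.58}
  criterion: 0
  n_signal: 360
  n_noise: 360
out_dir: megfusion_demo
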