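# Example comparative-study configuration (reduced replicate count).
# Load with read_experiment_config() and run with run_comparison().
specimens:
  brick1:
    kind: brick
    dims: [216.0, 99.0, 67.0]
    mass_kg: 3.13
  bird1:
    kind: bird
methods: [suspension, scales, volumetric, geometric]
suspension_positions: [3, 10]
scales_arms: [forward_only, forward_and_reversed]
n_replicates: 10
noise:
  marker_sigma: 1.32
  string_angle_sigma: 1.0
  attachment_offset_sigma: 0.0
  scale_reading_sigma: 0.0
  scale_quantum: 1.0e-4
  proximal_skew_delta: 5.0
seed: 42
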