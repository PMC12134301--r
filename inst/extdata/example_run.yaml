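# Desk-scale end-to-end run configuration (see run_config() for all fields).
seed: 1
augmentation:
  n_augment: 8
  angle_step: 45
training:
  epochs: 10
  batch_size: 4
  learning_rate: 0.001
test_set:
  mode: markerless
  angle_offset: 22.5
threshold: 0.10
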