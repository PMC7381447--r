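# Example run configuration: a small MIT-generated cohort, fully seeded.
seed: 7
output_dir: searchddm-output
design:
  n_blocks: 8
  trials_per_block: 32
generative:
  n_participants: 8
  model_id: MIT
  drift_rate: 0.0011
  noise_level: 0.03
  drift_rate_change: 0.0008
  cv: 0.2
preprocessing:
  min_rt: 200
  max_rt: 2000
  min_accuracy: 0.7
fitting:
  grid_n: 6
  nm_maxit: 30
analysis:
  min_cell_size: 10
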