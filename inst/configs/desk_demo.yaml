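# Desk-scale end-to-end demonstration on synthetic mouse-like motion.
seed: 7
data:
  synthetic:
    preset: mouse8
    n_recordings: 3
    frames: 1200
    missingness:
      n_gaps: 15
      length_support: [2, 5, 10, 20]
      length_prob: [0.4, 0.3, 0.2, 0.1]
split:
  mode: by_time
  fractions: [0.7, 0.15, 0.15]
samples:
  length: 60
  stride: 30
gaps: {}
model:
  backbone: transformer
  proba: true
  model_dim: 32
  n_layers: 2
  n_heads: 2
train:
  epochs: 30
  batch_size: 32
  switch_prob: 0.1
  n_missing: 1
eval:
  n_samples: 32
  pck_th: 0.01
impute:
  error_threshold: 0.5
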