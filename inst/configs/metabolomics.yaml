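# Metabolite-level flow benchmark: mean-field fluid model, lifted to 96
# dimensions. Keys mirror fluid_params(), ekatp_model(), train_config().
system:
  gamma: 0.1
  omega: 1.0
  A: -0.1
  lam: 10.0
  dt: 0.01
  T: 900
  init: [0.0, -0.01, 0.0]   # zeta1 preset; zeta2 is [0.01, -0.1, 0.5]
sigma: 0.0                  # sweep grid: 0.001 0.005 0.010 0.050 0.100 0.500
lift: 96
model:
  L: 16
  hidden: [256, 128]
  activation: tanh
train:
  k: 8
  epochs: 50
  batch_size: 64
  lr: 0.001
  train_steps: 800
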