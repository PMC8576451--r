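# Gene-expression-style chaotic benchmark: discrete Lorenz-type map, lifted
# to 96 dimensions. Keys mirror lorenz_params(), ekatp_model(), train_config().
system:
  eta: 10.0
  rho: 28.0
  beta: 2.6666666666666665
  h: 0.003           # nonlinearity level; the harder condition uses 0.006
  T: 1050
  init: [1.0, 1.0, 1.0]
sigma: 0.0           # conditions use 0.00 / 0.01
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
  train_steps: 1000
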