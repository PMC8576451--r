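# Proteomics-style oscillatory benchmark: nonlinear pendulum, lifted to 64
# dimensions. Keys mirror pendulum_params(), ekatp_model(), train_config().
system:
  g_over_l: 1.0
  theta0: 0.8        # complexity level h; the high-complexity condition uses 2.4
  theta_dot0: 0.0
  dt: 0.01
  T: 1600
sigma: 0.0           # noise intensity; conditions use 0.00 / 0.03 / 0.08
lift: 64
model:
  L: 16
  hidden: [128, 64]
  activation: tanh
train:
  k: 16          # = L: pins the operator spectrum for the 1000-step forecast
  epochs: 50
  batch_size: 64
  lr: 0.001
  train_steps: 600
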