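# Example training configuration (desk scale): Poisson network, 120 Hz drive
kind: train
kernel: medium
drive:
  r0: 20
  r1: 5
  f_mod: 120
network:
  n_neurons: 500
  k_ff: 100
  k_rec: 100
train:
  duration: 100
  eta: 2.0e-4
seeds:
  wiring: 1
  inputs: 2
  sim: 3
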