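# Default rat-scale parameter configuration (units: mm, ms, kPa, mV).
# Material blocks mirror the constitutive parameter names; pick one model
# per run.
units: mm-ms-kPa-mV

material:
  model: HO
  a: 0.0295        # kPa
  b: 8.023
  a_f: 9.236       # kPa
  b_f: 16.026
  a_s: 1.2405      # kPa
  b_s: 11.120
  a_fs: 0.108      # kPa
  b_fs: 11.436
  kappa: 10000     # kPa, near-incompressibility penalty

# polynomial alternatives:
#   model: TIC   with Lambda: 0.78, mu: 0.39, eta: 21.3
#   model: TII   with mu: 0.39, eta: 21.3, kappa: 10000

electro:
  alpha: 0.01
  c: 8
  I_ext: 0
  gamma: 0.012
  mu1: 0.2
  mu2: 0.3
  b_rec: 0.15
  k_phi: 100       # mV
  delta_phi: 80    # mV
  k_t: 12.9        # ms
  d_iso: 0.1       # mm^2/ms
  d_ani: 0.3       # mm^2/ms
  G_s: 10
  phi_s: 0.6

active:
  k_T: 0.49        # kPa/mV
  Phi_r: -80       # mV
  eps_0: 0.1       # 1/ms
  eps_inf: 1.0     # 1/ms
  xi: 0.1          # 1/mV
  Phi_bar: 0       # mV

solver:
  dt: 1            # ms
  t_end: 420       # ms
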