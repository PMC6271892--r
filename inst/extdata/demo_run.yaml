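# Demo: slit-smeared noisy scattering from a prolate micelle-sized
# particle (75 x 42 x 42 Angstrom), reduced and characterized end to end.
seed: 1
stages: [simulate, desmear, ift, shape, compare]
simulate:
  shape: prolate
  dims: [37.5, 21.0, 21.0]
  n_beads: 5000
  noise: 0.01
  smeared: true
  profile: {t1: 0.05, t_max: 0.2}
desmear:
  smooth_window: 11
  max_iter: 30
  tol: 1.0e-4
ift:
  dmax: 90
  n_basis: 20
  lambda: auto
  q_min_cut: 0.04
shape:
  floor_frac: 0.01
compare: {}
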