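# Parameters for the built-in classical pairwise backend
# (see read_backend_params()).
coulomb_constant: 332.0637
relative_dielectric: 40
coulomb_enabled: true
lj_enabled: true
lj_params:
  H: {epsilon: 0.016, sigma: 2.50}
  C: {epsilon: 0.086, sigma: 3.40}
  N: {epsilon: 0.170, sigma: 3.25}
  O: {epsilon: 0.210, sigma: 2.96}
  S: {epsilon: 0.250, sigma: 3.50}
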