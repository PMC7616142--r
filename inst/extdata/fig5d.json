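{
  "kappa_p": 1, "kappa_b": -8.5, "kappa_a": 1,
  "f_p": 0.8, "f_a": 1,
  "s0": 1.5, "w": 0.5,
  "eps_h": 0.15, "delta": 0.05,
  "model": "large_bending", "n_grid": 401
}
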