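{
  "seed": 42,
  "stages": ["synth", "fickian", "se", "hop", "fv"],
  "synth": {
    "truth_coefficients": [-15, 5, -1, 1],
    "rh_steps": [[70, 50], [50, 30], [30, 10]],
    "r0": 4e-06,
    "noise_sd": 0.005,
    "n_shells": 30,
    "n_times": 120,
    "two_state": {"k12": 1, "k21": 4, "emission_sd": 0.1, "dt": 1, "n_steps": 20000},
    "packing": {"n_spheres": 250, "radius": 0.15, "box": 3, "mode": "poisson"}
  },
  "fickian": {"order": 1, "n_shells": 30},
  "se": {"eta_coefficients": [9, -12], "a_w_grid": [0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7]},
  "hop": {"lag": 10, "candidates": [1, 2, 3], "n_bootstrap": 0},
  "fv": {"spacing": 0.05, "probe_radius": 0}
}
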