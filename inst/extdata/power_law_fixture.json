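{
  "comment": "Power-law growth fixture: a slow-coalescence mean-diameter trajectory: 20 log-spaced times over 60-5400 s with 2% multiplicative measurement noise.",
  "model": "power_law",
  "prefactor_um": 0.6,
  "beta": 0.16,
  "noise_rel": 0.02,
  "n_times": 20,
  "t_range_s": [60, 5400]
}
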