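{
  "comment": "Dynamic-scaling exponent fixtures: the growth-derived value implied by the measured growth exponent, and the larger value implied by the asymptotic width of the scaled size distribution.",
  "n_samples": 100000,
  "mean_d_um": 1.0,
  "growth_derived": { "alpha": 1.94 },
  "asymptotic_width": { "alpha": 3.8 }
}
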