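{
  "comment": "Mean-field Ostwald-ripening fixture: lognormal 10% initial polydispersity; the coarsening exponent is the log-log slope of mean radius over the late-time window, averaged over independent initial conditions.",
  "n_droplets": 10000,
  "mean_radius_um": 1.0,
  "sd_frac": 0.10,
  "K_L": 1.0,
  "t_end_s": 250,
  "n_snapshots": 40,
  "late_frac": 0.3,
  "n_runs": 5
}
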