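{
  "comment": "Barrier-mediated gel-point coagulation fixture: fractal merge rule df = 2 with a size-proportional Coulomb barrier; snapshots log-spaced; the mass-fractal fit runs over the regime where the number density has fallen below the stated fraction of its peak.",
  "n_seeds": 5000,
  "seed_diameter_um": 1.0,
  "alpha": 1.0,
  "df_merge": 2.0,
  "barrier_scale_kT": 0.2,
  "kernel_prefactor": 5e-7,
  "t_end_s": 3000,
  "snapshot_t_min_s": 30,
  "n_snapshots": 20,
  "sampled_volume_mL": 1e-4,
  "detection_band_um": [0.5, 10],
  "coarsening_density_fraction": 0.3333333333
}
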