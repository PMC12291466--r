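# condkit

Population analysis and growth kinetics of biomolecular condensates
measured by holographic video microscopy.

Label-free holographic characterization records, for every condensate
droplet flowing through the instrument, a diameter *d*<sub>p</sub> and a
refractive index *n*<sub>p</sub> — an optical proxy for the protein
concentration in the droplet's dense phase — plus absolute number
densities from a known interrogated volume. `condkit` is for researchers
who have (or simulate) such per-droplet tables and want to answer three
questions about a condensate system:

1. **What is in the droplets?** Effective-medium theory (Lorentz–Lorenz
   or linear *dn/dc* mixing rules) converts *n*<sub>p</sub> into a
   dense-phase volume fraction φ and mass concentration
   *c* = 1000 φ / v̄ (mg/mL).
2. **How do they grow?** Three candidate mechanisms are fitted and
   ranked:
   - *coalescence* — power-law growth ⟨*d*<sub>p</sub>(*t*)⟩ ∼ *t*<sup>β</sup>
     with the Smoluchowski dynamic-scaling distribution
     *P*(*d*<sub>p</sub>) = [2*W*/Γ(α+1)] (*W d*<sub>p</sub>/⟨*d*<sub>p</sub>⟩)<sup>2α+1</sup>
     exp(−*W*²*d*<sub>p</sub>²/⟨*d*<sub>p</sub>⟩²) / ⟨*d*<sub>p</sub>⟩,
     *W*(α) = (α+1)Γ(α+3/2)/Γ(α+2), and the exponent relation
     β = 1/(2(α+1));
   - *Ostwald ripening* — the Lifshitz–Slyozov–Wagner reference β = 1/3,
     tested by z-score against the fitted β;
   - *self-regulated (gel-point) coagulation* — logarithmic growth
     ⟨*d*<sub>p</sub>(*t*)⟩ = *d*₀ [ln((*t*−*t*₀)/*t*₀ + e)]<sup>1/*d*<sub>f</sub></sup>
     with the mass–fractal companion
     ⟨*d*<sub>p</sub>⟩ = *d*₀ (*n*₀/*n*(*t*))<sup>1/*d*<sub>f</sub></sup>.
3. **Is the population at equilibrium, and is the measurement
   reproducible?** The distance correlation dCorr(*n*<sub>p</sub>, *d*<sub>p</sub>)
   with bootstrap errors serves as a disequilibrium proxy (at equilibrium,
   composition is independent of size), and the Jensen–Shannon divergence
   (log base 2, so 0 ≤ JSD ≤ 1) scores run-to-run reproducibility.

A fourth module analyzes subdiffraction structure and dynamics inside
condensates: first-principles DBSCAN clustering of single-molecule
localizations and temporal image correlation (TICS) maps/histograms that
separate static from mobile regions in fluorescence image stacks.

Every estimator is testable end-to-end against simulators with known
ground truth: exact event-driven Smoluchowski coagulation (Brownian
kernel, fractal merge rule, size-dependent Coulomb barrier, nucleation),
a volume-conserving mean-field LSW ripening integrator, a holographic
measurement model (band truncation, noise, index assignment), and
localization/image-stack fixture generators.

## Worked example

Simulate a gel-point coagulation experiment (fractal merge rule
*d*<sub>f</sub> = 2, size-proportional barrier), pass it through the
holographic measurement model, and run the growth study:

```r
library(condkit)

cfg <- sim_config(n_seeds = 3000, df_merge = 2, alpha = 1,
                  barrier_scale_kT = 0.2, kernel_prefactor = 8e-7,
                  t_end_s = 3000,
                  snapshot_times_s = exp(seq(log(30), log(3000),
                                             length.out = 12)),
                  rng_seed = 42)
truth    <- simulate_coagulation(cfg)
mm       <- measurement_model(sigma_d_rel = 0.02, sigma_n = 5e-5,
                              phi_dense = 0.05, phi_spread = 0.003)
measured <- apply_measurement_model(truth, mm, seed = 42)

report <- run_growth_study(measured, band = c(0.5, 10))
print(report$comparison)
#> Growth-mechanism comparison (AICc, lower is better):
#>   power_law       AICc =   -63.41
#>   self_regulated  AICc =   -56.30
#>   lsw_reference   AICc =   -40.02
#>   beta = 0.1578 +/- 0.0197; z vs LSW 1/3 = -8.93 (LSW rejected)
#>   collapse test: max pairwise JSD = 0.9376 bits
print(report$mass_fractal)
#> Mass-fractal fit: d_f = 2.130 +/- 0.018  (slope 0.4694, n0 = 2.675e+07 /mL)
```

Reading the output: the measured growth exponent β ≈ 0.158 is far below
the ripening value (z = −8.9 rejects LSW), the scaled size distributions
fail to collapse (max pairwise JSD 0.94 bits, so simple dynamic scaling
is out), and the diameter–density relation returns a fractal dimension
*d*<sub>f</sub> ≈ 2.13 ± 0.02 — recovering the *d*<sub>f</sub> = 2
merge rule the simulation was built with, the signature of gel-point
cluster growth.

Population-level characterization of the final snapshot:

```r
s  <- measured$snapshots[[12]]
st <- population_stats(s)
number_density(s)$density_per_mL      # 2.74e+06 droplets per mL
st$mean_n                             # 1.35193  mean refractive index
volume_fraction_from_index(st$mean_n) # 0.0500   dense-phase volume fraction
bootstrap_dcorr(s, n_boot = 500, seed = 1)
#> dCorr(n_p, d_p) = 0.078 +/- 0.020 (bootstrap, B = 500, n = 274)
```

The recovered φ = 0.050 matches the measurement model's configured
dense-phase fraction, and the small dCorr(*n*<sub>p</sub>, *d*<sub>p</sub>)
reflects a uniform-composition (equilibrium-like) population.

See `vignettes/condensate-analysis.Rmd` for the models, their
assumptions, and all numerical choices.

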