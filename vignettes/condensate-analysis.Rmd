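---
title: "Characterizing condensate populations and discriminating their growth mechanisms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing condensate populations and discriminating their growth mechanisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condkit)
```

## The measurement and its data model

Holographic video microscopy characterizes individual colloidal particles
in flow: fitting light-scattering theory to each recorded hologram yields,
per droplet, a diameter $d_p$ and a refractive index $n_p$, without labels
or surface attachment. For biomolecular condensates this is powerful
because $n_p$ is an optical proxy for the protein concentration inside the
droplet, and because the technique counts droplets in a known interrogated
volume, giving absolute number densities. Detection efficiency is close to
unity for $0.5\,\mu m \le d_p \le 10\,\mu m$, which is why every
population-level statistic in this package is computed after an explicit,
inclusive detection-band filter (`filter_detection_band()`, default
$[0.5, 10]\,\mu m$).

The package's atom is the per-droplet record $(d_p, n_p, t, z)$; records
sharing a time bin form a `population_snapshot` carrying the sampling
metadata (interrogated volume, medium index $n_m = 1.340$ at 450 nm);
ordered snapshots form a `condensate_timeseries`. Records carry exact
acquisition times and snapshots are formed by a configurable bin width
(default 60 s): instruments report continuous streams, and a one-minute
bin matches the rate at which a statistically useful sample (hundreds to
thousands of droplets) accumulates. On-disk, datasets are plain CSV with a
`#`-commented `key=value` header; the writer stores six decimal places,
which over-resolves the instrument's $10^{-5}$ index resolution.

One documented assumption: where a population's mean index is quoted with
an uncertainty of a few $10^{-5}$, we treat that figure as the standard
error of the mean, not the population standard deviation; the simulators
expose the population spread (`phi_spread`, `sigma_n`) separately.

## From refractive index to concentration

The mean dense-phase composition is obtained by effective-medium theory.
Two mixing rules are implemented (`mixing_params()`):

* **Lorentz–Lorenz** (default): the Lorenz factor
  $L(n) = (n^2-1)/(n^2+2)$ of the droplet is the volume-fraction-weighted
  mean of the factors of pure protein and medium. Inversion is algebraic,
  so $\phi \to n_p \to \phi$ round-trips to $10^{-10}$ or better.
* **Linear $dn/dc$**: $\phi = \bar v\,(n_p - n_m)/(dn/dc)$, the tangent of
  the first rule at $\phi = 0$ when $dn/dc$ is set consistently.

Mass concentration follows as $c = 1000\,\phi/\bar v$ (mg/mL). Defaults —
anhydrous protein index 1.60, partial specific volume
$\bar v = 0.73$ mL/g, $dn/dc = 0.19$ mL/g — are conventional protein
optics values, deliberately not tuned to any particular dataset; users
measuring a specific protein should supply its values. Indexes slightly
below $n_m$ (within tolerance) clamp to $\phi = 0$; indexes further below
signal a dilute-phase or corrupt record and raise an error rather than
returning a negative fraction.

## Three growth mechanisms and how we tell them apart

Condensate coarsening admits at least three mechanisms with distinct
quantitative signatures.

**Coalescence (Smoluchowski kinetics with dynamic scaling).** If droplets
merge at diffusion-limited rates with $D(d_p) \sim d_p^{-\alpha}$, the
mean diameter grows as $\langle d_p\rangle \sim t^\beta$ with
$\beta = 1/(2(\alpha+1))$, and the scaled size distribution approaches

$$P(d_p) = \frac{2W}{\Gamma(\alpha+1)}
  \left(\frac{W d_p}{\langle d_p\rangle}\right)^{2\alpha+1}
  e^{-W^2 d_p^2/\langle d_p\rangle^2}\Big/\langle d_p\rangle,
  \qquad W(\alpha) = \frac{(\alpha+1)\,\Gamma(\alpha+3/2)}{\Gamma(\alpha+2)}.$$

`fit_power_law()` estimates $\beta$ by weighted least squares on the
log–log scale (weights $(\langle d\rangle/SE)^2$, the inverse variance of
the log-transformed means; unweighted fallback when SEs are absent).
`fit_smoluchowski_alpha()` estimates $\alpha$ by maximum likelihood with
the scale profiled at the sample mean — the same normalization used when
size distributions are rescaled by their measured mean — with the SE from
the observed information. Internal consistency of a coalescence
interpretation requires the $\alpha$ implied by $\beta$ through the
relation above (`beta_alpha_relation()`) to agree with the $\alpha$ fitted
from the distribution shape, and requires the mean-rescaled distributions
to collapse (`scaling_collapse()`, scored as the maximum pairwise
Jensen–Shannon divergence between scaled histograms). Note that a
measured $\beta = 0.16$ inverts to $\alpha = 2.125$; published analyses
quoting $\alpha \approx 1.94 \pm 0.10$ evidently invert an unrounded
$\beta \approx 0.17$. The package performs the exact inversion and leaves
reconciliation to the user.

**Ostwald ripening (LSW).** Diffusive exchange of monomers predicts
$\beta = 1/3$. Rather than fitting a second free power law, the package
treats ripening as a fixed-exponent reference: `compare_growth_models()`
reports the z-score of the fitted $\beta$ against $1/3$ and includes the
pinned-exponent model in the ranking.

**Self-regulated (gel-point) coagulation.** When a Coulomb barrier grows
with aggregate size, growth slows to logarithmic:

$$\langle d_p(t)\rangle = d_0\,\bigl[\ln\bigl((t-t_0)/t_0 + e\bigr)\bigr]^{1/d_f},$$

so the mean size is exactly $d_0$ at the onset time $t_0$ (the $+e$
anchor). The companion mass–fractal relation
$\langle d_p\rangle = d_0 (n_0/n(t))^{1/d_f}$ links the declining number
density to the growing mean size; `fit_mass_fractal()` recovers $d_f$ as
the inverse slope of $\ln\langle d_p\rangle$ against $\ln(n_0/n)$, with a
delta-method SE. The typeset form of the logarithmic law is ambiguous in
some sources about where $d_f$ enters; we adopt the power-outside-the-log
form above because it alone (i) reduces to $d_0$ at $t_0$ and (ii) is
consistent with the mass–fractal relation plus logarithmically decreasing
concentration. The alternative reading
$d_0 \ln((t-t_0)/(t_0 d_f) + e)$ remains available via
`form = "inner_df"` in `fit_self_regulated()`. All model logarithms are
natural logs — the $+e$ anchor forces this.

`compare_growth_models()` ranks the three candidates by the
small-sample-corrected Akaike criterion computed from residuals on the
log-diameter scale (2 parameters for the free power law, 1 for the pinned
LSW reference, 2–3 for the logarithmic law). AICc was chosen because
growth studies typically have 8–20 time points, squarely in the
small-sample regime; the underlying narrative comparison in the
literature is qualitative, so a ranking criterion had to be chosen here.

## What the simulators emulate — and what they do not

The package is testable end-to-end because every statistical structure
the estimators assume can be generated with known ground truth.

**Stochastic coagulation** (`simulate_coagulation()`) is an exact
event-driven simulation of the Brownian kernel
$K(d_i,d_j) = C\,(d_i^{-\alpha}+d_j^{-\alpha})(d_i+d_j)$, implemented by
thinning against a kernel upper bound so proposals cost O(1): uniform
candidate pairs, exponential waiting times at the bounding rate,
acceptance $K/K_{max}$ times the barrier factor
$\exp(-b\,(d_i+d_j)/2d_{seed})$. The merge rule
$d = (d_i^{d_f}+d_j^{d_f})^{1/d_f}$ makes $\sum d^{d_f}$ an exact
invariant — volume for liquid droplets ($d_f = 3$), a gel-point fractal
mass for $d_f = 2$. The barrier law is linear in the pair's mean diameter
because the literature states only that the barrier *increases* with
aggregate size; the coefficient is an explicit config knob. Nucleation
injects seed-size droplets at a constant rate until a stop time,
mirroring the observation that detectable droplet numbers keep rising for
tens of minutes after triggering. A classical caveat, surfaced rather
than hidden: for the Brownian kernel with $\alpha = 1$ the homogeneity
class gives $\beta = 1/3$, not the $1/4$ of the dynamic-scaling relation
above, so the simulator reports its empirical exponent rather than
asserting the relation.

**Mean-field ripening** (`simulate_lsw()`) integrates
$\dot a_i = (K/a_i)(1/a_c - 1/a_i)$ with the critical radius recomputed
each step from volume conservation (for this law, $a_c=\langle a\rangle$).
The update runs in volume space, where the conservation constraint is
linear in the state, and a conservative projection after removing
dissolved droplets keeps total condensed volume exact to machine
precision; the largest pre-projection step error (about $10^{-4}$
relative at the default `dt_frac = 0.005`) is reported on the result.
Droplets are removed when they shrink below a small threshold radius
(default 0.02 of the initial mean), the standard regularization of the
finite-time dissolution singularity.

**The measurement model** (`apply_measurement_model()`) applies what the
instrument does to truth: multiplicative diameter noise, a per-droplet
dense-phase volume fraction drawn around `phi_dense`, the effective-medium
forward map plus additive index noise, inclusive band truncation, and
Bernoulli subsampling (with the sampled volume rescaled so densities stay
unbiased). Band truncation is the one bias the fits must tolerate: when
sub-band droplets exist, the measured mean exceeds the true mean, and the
tests pin this direction.

What the generators do **not** emulate: spatial correlations in the flow
cell, droplet tracking across frames (the instrument measures
populations, not trajectories), polydisperse refractive-index gradients
within single droplets, and hologram-level noise. Passing tests therefore
validate the estimators against their stated statistical models, not
against raw-instrument artifacts.

**Subdiffraction fixtures.** Localization sets are Gaussian clusters on a
jittered grid plus uniform background; image stacks are a static pattern
plus, inside a mobile mask, white (fast) fluctuations and optionally an
AR(1)-correlated slow component. The lag-1 temporal correlation of a
mobile pixel is then $\rho\,\sigma^2_{slow}/(\sigma^2_{slow} +
\sigma^2_{fast})$, so raising the fast variance monotonically lowers
correlation — the knob that emulates increasingly dynamic condensate
interiors. A purely white mobile component produces near-binary maps
(1 or $\approx 0$); intermediate correlation values require temporally
persistent dynamics, which is physically the point.

## Disequilibrium and reproducibility metrics

`distance_correlation()` implements the sample distance correlation from
first principles (pairwise distance matrices, double centering,
$dCov^2/\sqrt{dVar_x\,dVar_y}$); the population statistic vanishes iff
the variables are independent, which justifies using
$dCorr(n_p, d_p)$ as a proxy for distance from equilibrium — at
equilibrium all droplets share one dense-phase concentration regardless
of size. Constant marginals return 0 by convention. Uncertainty comes
from a droplet-level bootstrap (default 1000 resamples, percentile
intervals); `dcorr_timecourse()` sweeps snapshots for
relaxation/perturbation curves, collecting per-snapshot failures rather
than aborting.

`jensen_shannon()` scores run-to-run reproducibility of measured
distributions: shared bin edges over the pooled range (Freedman–Diaconis
by default, configurable because published analyses rarely state their
binning), additive smoothing $\varepsilon = 10^{-12}$, logarithms base 2
so the divergence lies in $[0,1]$ with 1 attained on disjoint supports —
the natural scale on which reported scores like 0.02 (holographic) versus
0.40 (surface-attached imaging) are read.

## Subdiffraction structure and dynamics

`dbscan_cluster()` is the original density-reachability algorithm written
out (core points by neighborhood counts, BFS cluster expansion over
cores, borders attached, everything else noise); no clustering library is
involved, and the tests compare the partition against an independent
reachability-closure oracle. `tics_map()` computes per-pixel Pearson
correlation between a pixel's intensity series and its lagged copy
(default lag 1 frame at 20 ms). The Pearson form was chosen over the
unbounded fluctuation-normalized image-correlation estimator because it
is bounded in $[-1,1]$ and directly comparable across conditions; pixels
with zero temporal variance are static by definition and assigned
correlation 1 with a constancy flag. `tics_histogram()` normalizes to
unit area over $[-1,1]$ (50 bins by default) for cross-condition
comparison; multi-lag sweeps are a loop over `lag_frames`.

## Numerical choices and degenerate inputs

* Smoluchowski sampling uses the exact gamma representation
  ($d = \mu\sqrt{X}/W$, $X \sim \Gamma(\alpha+1,1)$), not
  accept–reject, so draws are cheap and reproducible.
* The $\alpha$ MLE searches $(-0.95, 30)$; hitting the boundary raises an
  error instead of returning a silently clipped estimate. All-equal
  samples raise a convergence error.
* The logarithmic-law fit uses Levenberg–Marquardt with positivity
  bounds; failures carry the optimizer's message rather than a silent NA.
* Single-record snapshots report SE 0 with an explicit degeneracy flag;
  empty snapshots are errors for statistics but legal for filtering.
* Zero-count snapshots report density 0 with a one-count upper bound.
* Bootstrap with a single resample reports SE 0, flagged degenerate.

## Problem sizes used in the shipped checks

The packaged study conditions are: $10^4$ droplets with 10% lognormal
polydispersity integrated to $t = 250$ (in units where $K = 1$ and the
initial mean radius is 1) for the ripening exponent, averaged over 5
initial conditions with the late-time window $t \ge 0.3\,t_{end}$; 20
log-spaced times over 60–5400 s with 2% multiplicative noise, averaged
over 50 noise realizations, for the growth exponent; $10^5$ draws for
each $\alpha$ recovery; and $5\times10^3$ seed droplets coagulating under
the $d_f = 2$ merge rule with barrier coefficient 0.2 for the fractal
dimension, fitted where the number density has fallen below a third of
its peak (the post-transient coarsening regime, inside the detection
band). These sizes give recovery uncertainties comfortably below the
tolerances asserted in the test suite.

## Known limitations

* The effective-medium defaults are generic protein values; absolute
  concentrations are only as good as the supplied $\bar v$, protein
  index, or $dn/dc$.
* The dynamic-scaling MLE profiles the scale at the sample mean; for very
  small samples a joint likelihood would be preferable.
* The coagulation simulator is spatially homogeneous (mean-field pair
  rates); it cannot emulate diffusion-limited spatial gradients.
* Distance correlation is used descriptively, as in the source analyses;
  no permutation-test calibration is shipped.
* The LSW integrator's conservative projection redistributes dissolved
  droplets' residual volume proportionally to droplet volume, a
  mean-field simplification of the true monomer flux.
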