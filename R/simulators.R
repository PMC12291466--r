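#' Configuration of a stochastic coagulation run
#'
#' Describes one synthetic coagulation experiment. Droplets collide and
#' merge at a diffusion-limited pair rate
#' \eqn{K(d_i, d_j) = C\,(d_i^{-\alpha} + d_j^{-\alpha})(d_i + d_j)}
#' (Brownian kernel with the diffusion coefficient scaling as
#' \eqn{D \sim d^{-\alpha}}). On merging, sizes combine through the
#' mass-fractal rule \eqn{d = (d_i^{d_f} + d_j^{d_f})^{1/d_f}};
#' \code{df_merge = 3} conserves droplet volume (liquid coalescence) while
#' \code{df_merge = 2} models gel-point fractal clusters. A Coulomb-type
#' barrier that grows with aggregate size can throttle late coagulation
#' (self-regulation): merges are accepted with probability
#' \eqn{\exp(-b\,(d_i+d_j)/(2 d_{seed}))} with \eqn{b} in units of kT.
#' Fresh seed-size droplets nucleate at a constant rate until
#' \code{t_nuc_stop_s}, mirroring the several-minute nucleation phase seen
#' after condensation is triggered.
#'
#' @param n_seeds initial droplet count (>= 1).
#' @param seed_diameter_um nucleus diameter, micrometers.
#' @param alpha diffusion-scaling exponent (> -1); 1 is the Stokes value.
#' @param df_merge fractal dimension of the merge rule (> 0).
#' @param barrier_scale_kT barrier coefficient \eqn{b}; 0 disables
#'   self-regulation.
#' @param kernel_prefactor rate constant \eqn{C}, 1/(um * s) scale.
#' @param nucleation_rate_per_s new seed droplets per second.
#' @param t_nuc_stop_s time at which nucleation ceases, seconds.
#' @param t_end_s simulated duration, seconds.
#' @param snapshot_times_s times at which population snapshots are emitted;
#'   default a log-spaced grid of 15 times ending at \code{t_end_s}.
#' @param event_cap maximum number of proposal events before the run is
#'   truncated with a warning.
#' @param sampled_volume_mL nominal fluid volume the simulated population
#'   occupies (sets the number-density scale).
#' @param rng_seed integer seed; runs are bit-reproducible given the seed.
#' @return object of class \code{"sim_config"}.
#' @export
sim_config <- function(n_seeds = 1000,
                       seed_diameter_um = 1,
                       alpha = 1,
                       df_merge = 3,
                       barrier_scale_kT = 0,
                       kernel_prefactor = 1e-3,
                       nucleation_rate_per_s = 0,
                       t_nuc_stop_s = 0,
                       t_end_s = 3600,
                       snapshot_times_s = NULL,
                       event_cap = 2e6,
                       sampled_volume_mL = 1e-4,
                       rng_seed = 1) {
  if (n_seeds < 1) stop("n_seeds must be at least 1", call. = FALSE)
  if (df_merge <= 0) stop("df_merge must be positive", call. = FALSE)
  if (alpha <= -1) stop("alpha must exceed -1", call. = FALSE)
  if (nucleation_rate_per_s < 0 || kernel_prefactor < 0 ||
      barrier_scale_kT < 0) {
    stop("rates and the barrier coefficient must be non-negative",
         call. = FALSE)
  }
  if (is.null(snapshot_times_s)) {
    snapshot_times_s <- exp(seq(log(t_end_s / 100), log(t_end_s),
                                length.out = 15))
  }
  structure(list(n_seeds = as.integer(n_seeds),
                 seed_diameter_um = seed_diameter_um,
                 alpha = alpha, df_merge = df_merge,
                 barrier_scale_kT = barrier_scale_kT,
                 kernel_prefactor = kernel_prefactor,
                 nucleation_rate_per_s = nucleation_rate_per_s,
                 t_nuc_stop_s = t_nuc_stop_s,
                 t_end_s = t_end_s,
                 snapshot_times_s = sort(snapshot_times_s),
                 event_cap = event_cap,
                 sampled_volume_mL = sampled_volume_mL,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

# snapshot of the current simulator state as a population_snapshot;
# refractive index is NA until a measurement model assigns composition
truth_snapshot <- function(d, t, config) {
  rec <- data.frame(replicate_id = "sim",
                    time_s = rep(t, length(d)),
                    droplet_id = seq_along(d),
                    diameter_um = d,
                    refractive_index = NA_real_,
                    z_um = NA_real_)
  population_snapshot(droplet_records(rec),
                      sampled_volume_mL = config$sampled_volume_mL,
                      time_bin = c(t, t))
}

#' Event-driven stochastic coagulation
#'
#' Exact stochastic simulation of pairwise coagulation under the Brownian
#' kernel described in [sim_config()], using thinning (rejection) against
#' a kernel upper bound so each proposal costs O(1): candidate pairs are
#' drawn uniformly, waiting times from the bounding rate, and proposals
#' accepted with probability \eqn{K(d_i,d_j)\,e^{-E_b/kT}/K_{max}}.
#' Snapshots of the population are emitted on the configured time grid.
#'
#' Without nucleation, the merge rule conserves \eqn{\sum d^{d_f}}
#' exactly, so total droplet volume is conserved when
#' \code{df_merge = 3}.
#'
#' @param config a [sim_config()].
#' @return a \code{condensate_timeseries} of ground-truth snapshots, with
#'   attributes \code{config}, \code{n_merges}, \code{n_proposals} and
#'   \code{truncated}.
#' @export
simulate_coagulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  d <- rep(config$seed_diameter_um, config$n_seeds)
  t <- 0
  C <- config$kernel_prefactor
  alpha <- config$alpha
  dfm <- config$df_merge
  b <- config$barrier_scale_kT
  d_seed <- config$seed_diameter_um
  nu <- config$nucleation_rate_per_s
  grid <- config$snapshot_times_s
  snaps <- vector("list", length(grid))
  gi <- 1L
  dmin <- min(d); dmax <- max(d)
  n_prop <- 0L; n_merge <- 0L; truncated <- FALSE

  emit_until <- function(tt) {
    while (gi <= length(grid) && grid[gi] <= tt) {
      snaps[[gi]] <<- truth_snapshot(d, grid[gi], config)
      gi <<- gi + 1L
    }
  }

  repeat {
    n <- length(d)
    npairs <- n * (n - 1) / 2
    Dmax <- if (alpha > 0) dmin^(-alpha) else dmax^(-alpha)
    kmax <- C * 2 * Dmax * 2 * dmax
    lam_coag <- npairs * kmax
    lam_nuc <- if (t < config$t_nuc_stop_s) nu else 0
    lam <- lam_coag + lam_nuc
    if (lam <= 0) { t <- config$t_end_s; emit_until(t); break }
    dt <- stats::rexp(1, lam)
    if (t + dt > config$t_end_s) { emit_until(config$t_end_s); break }
    t <- t + dt
    emit_until(t)
    n_prop <- n_prop + 1L
    if (n_prop > config$event_cap) {
      warning("event cap exhausted at t = ", signif(t, 4),
              " s; returning partial run")
      truncated <- TRUE
      emit_until(config$t_end_s)
      break
    }
    if (stats::runif(1) < lam_nuc / lam) {
      d <- c(d, d_seed)
      dmin <- min(dmin, d_seed); dmax <- max(dmax, d_seed)
      next
    }
    if (n < 2L) next
    ij <- sample.int(n, 2L)
    di <- d[ij[1]]; dj <- d[ij[2]]
    k <- C * (di^(-alpha) + dj^(-alpha)) * (di + dj)
    acc <- k / kmax
    if (b > 0) acc <- acc * exp(-b * (di + dj) / (2 * d_seed))
    if (stats::runif(1) < acc) {
      dnew <- (di^dfm + dj^dfm)^(1 / dfm)
      d <- c(d[-ij], dnew)
      n_merge <- n_merge + 1L
      dmax <- max(dmax, dnew)
      if (di <= dmin || dj <= dmin) dmin <- min(d)
    }
  }
  # grid times the loop never reached (e.g. single droplet left)
  emit_until(config$t_end_s)
  got <- !vapply(snaps, is.null, logical(1))
  out <- condensate_timeseries(snaps[got], label = "coagulation simulation")
  attr(out, "config") <- config
  attr(out, "n_merges") <- n_merge
  attr(out, "n_proposals") <- n_prop
  attr(out, "truncated") <- truncated
  out
}

#' Mean-field Ostwald ripening (LSW) trajectory
#'
#' Integrates the Lifshitz-Slyozov-Wagner per-particle growth law
#' \deqn{\frac{da_i}{dt} = \frac{K}{a_i}\left(\frac{1}{a_c} -
#'   \frac{1}{a_i}\right)}
#' for a polydisperse population of radii \eqn{a_i}. The critical radius
#' \eqn{a_c} is recomputed every step as the value that makes the total
#' droplet volume instantaneously conserved (for this law,
#' \eqn{a_c = \langle a\rangle}), and the update is performed in volume
#' space, where the conservation constraint is linear in the state, with a
#' conservative projection after droplet removal, so total condensed
#' volume is conserved to machine precision throughout. Droplets
#' shrinking below \code{kill_radius} dissolve: they are removed, their
#' residual volume returned to the population. Deterministic given the
#' initial radii; the lognormal initial condition is drawn from
#' \code{rng_seed}. At late times the mean radius approaches the
#' classical \eqn{t^{1/3}} coarsening law.
#'
#' @param n_droplets initial droplet count.
#' @param mean_radius_um initial mean radius.
#' @param sd_frac lognormal polydispersity (sd/mean) of the initial radii;
#'   must be positive, since a perfectly monodisperse population has no
#'   ripening driving force (a warning is raised and the population
#'   stagnates).
#' @param K_L rate constant of the growth law, um^3/s scale.
#' @param t_end_s integration horizon, seconds.
#' @param n_snapshots number of log-spaced output times.
#' @param dt_frac time step as a fraction of the coarsening time
#'   \eqn{a_c^3/K}; controls the integration (and volume-conservation)
#'   tolerance.
#' @param kill_radius_um removal threshold for dissolving droplets.
#' @param rng_seed seed for the initial condition.
#' @return object of class \code{"lsw_trajectory"}: data.frame
#'   \code{series} (time_s, mean_radius_um, n, volume), final radii,
#'   \code{volume_drift} (relative conservation error of the final state),
#'   \code{max_step_volume_error} (largest single-step error before
#'   projection) and the call parameters.
#' @export
simulate_lsw <- function(n_droplets = 10000,
                         mean_radius_um = 1,
                         sd_frac = 0.10,
                         K_L = 1,
                         t_end_s = 250,
                         n_snapshots = 40,
                         dt_frac = 0.005,
                         kill_radius_um = 0.02,
                         rng_seed = 1) {
  if (sd_frac < 0) stop("sd_frac must be non-negative", call. = FALSE)
  set.seed(rng_seed)
  if (sd_frac == 0) {
    warning("monodisperse initial condition: no ripening driving force")
    a <- rep(mean_radius_um, n_droplets)
  } else {
    sl <- sqrt(log(1 + sd_frac^2))
    a <- stats::rlnorm(n_droplets, log(mean_radius_um) - sl^2 / 2, sl)
  }
  v0 <- sum(a^3)
  removed <- 0
  grid <- exp(seq(log(t_end_s / 200), log(t_end_s), length.out = n_snapshots))
  series <- data.frame(time_s = numeric(0), mean_radius_um = numeric(0),
                       n = integer(0), volume = numeric(0))
  record <- function(tt) {
    series[nrow(series) + 1L, ] <<- list(tt, mean(a), length(a), sum(a^3))
  }
  # integrate in volume space: v = a^3 obeys dv/dt = 3K(a/a_c - 1), whose
  # population sum vanishes identically for a_c = <a>. Droplets crossing
  # the dissolution threshold carry only a residual O(v_kill) volume; the
  # step error this causes is repaired by a conservative projection
  # (rescaling survivor volumes to the exact invariant), the standard
  # conservative remap. The largest pre-projection step error is reported.
  v <- a^3
  v_kill <- kill_radius_um^3
  max_step_err <- 0
  t <- 0; gi <- 1L
  while (t < t_end_s && length(v) > 1L) {
    a <- v^(1 / 3)
    a_c <- mean(a)
    dvdt <- 3 * K_L * (a / a_c - 1)
    dt <- min(dt_frac * a_c^3 / K_L, t_end_s - t)
    v <- v + dt * dvdt
    dead <- v <= v_kill
    if (any(dead)) {
      removed <- removed + sum(pmax(v[dead], 0))
      v <- v[!dead]
      if (length(v) < 2L) break
    }
    max_step_err <- max(max_step_err, abs(sum(v) - v0) / v0)
    v <- v * (v0 / sum(v))
    t <- t + dt
    a <- v^(1 / 3)
    while (gi <= length(grid) && grid[gi] <= t) {
      record(grid[gi]); gi <- gi + 1L
    }
  }
  a <- v^(1 / 3)
  while (gi <= length(grid)) { record(grid[gi]); gi <- gi + 1L }
  structure(list(series = series,
                 radii_um = a,
                 volume_drift = abs(sum(a^3) - v0) / v0,
                 max_step_volume_error = max_step_err,
                 residual_removed_frac = removed / v0,
                 params = list(n_droplets = n_droplets,
                               mean_radius_um = mean_radius_um,
                               sd_frac = sd_frac, K_L = K_L,
                               t_end_s = t_end_s, dt_frac = dt_frac,
                               kill_radius_um = kill_radius_um,
                               rng_seed = rng_seed)),
            class = "lsw_trajectory")
}

#' @export
print.lsw_trajectory <- function(x, ...) {
  s <- x$series
  cat(sprintf(
    "LSW ripening run: %d -> %d droplets, <a> %.3f -> %.3f um, drift %.2e\n",
    x$params$n_droplets, s$n[nrow(s)], s$mean_radius_um[1],
    s$mean_radius_um[nrow(s)], x$volume_drift))
  invisible(x)
}

#' Late-time coarsening exponent of an LSW run
#'
#' Log-log slope of mean radius against time over the late-time window,
#' for comparison with the theoretical LSW exponent 1/3.
#' @param traj an [simulate_lsw()] result.
#' @param late_frac use times greater than \code{late_frac * t_end}.
#' @return a \code{power_law_fit} on the selected window.
#' @export
lsw_exponent <- function(traj, late_frac = 0.3) {
  stopifnot(inherits(traj, "lsw_trajectory"))
  s <- traj$series
  keep <- s$time_s >= late_frac * max(s$time_s)
  fit_power_law(s$time_s[keep], s$mean_radius_um[keep])
}

#' Synthetic mean-diameter trajectory from a named growth model
#'
#' Direct fixture generator for parameter-recovery tests of the power-law
#' and self-regulated fitters: evaluates the chosen model on a log-spaced
#' time grid, applies multiplicative Gaussian noise and returns synthetic
#' standard errors consistent with the noise level.
#'
#' @param model \code{"power_law"} (params \code{prefactor}, \code{beta})
#'   or \code{"self_regulated"} (params \code{d0}, \code{t0}, \code{df}).
#' @param params named list of model parameters.
#' @param noise_rel relative (multiplicative) noise standard deviation.
#' @param n_times number of time points.
#' @param t_range time span, seconds.
#' @param seed integer seed.
#' @return list with \code{times}, \code{mean_diams}, \code{ses},
#'   \code{truth} (noiseless values), \code{model}, \code{params}.
#' @export
sample_model_trajectory <- function(model = c("power_law", "self_regulated"),
                                    params = list(),
                                    noise_rel = 0.02,
                                    n_times = 20,
                                    t_range = c(60, 5400),
                                    seed = NULL) {
  model <- match.arg(model)
  times <- exp(seq(log(t_range[1]), log(t_range[2]), length.out = n_times))
  truth <- if (model == "power_law") {
    p <- params$prefactor %||% 1
    beta <- params$beta %||% 0.16
    if (p <= 0) stop("prefactor must be positive", call. = FALSE)
    p * times^beta
  } else {
    d0 <- params$d0 %||% 1
    t0 <- params$t0 %||% 300
    dfp <- params$df %||% 2
    if (d0 <= 0 || t0 <= 0 || dfp <= 0) {
      stop("d0, t0, df must be positive", call. = FALSE)
    }
    self_regulated_mean(times, d0, t0, dfp)
  }
  if (!is.null(seed)) set.seed(seed)
  noisy <- if (noise_rel > 0) {
    truth * pmax(1 + noise_rel * stats::rnorm(n_times), 0.05)
  } else truth
  ses <- if (noise_rel > 0) noise_rel * noisy else rep(0, n_times)
  list(times = times, mean_diams = noisy, ses = ses,
       truth = truth, model = model, params = params,
       noise_rel = noise_rel, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Holographic measurement model
#'
#' What the instrument does to ground truth: multiplicative diameter
#' noise, assignment of a refractive index from a per-droplet dense-phase
#' volume fraction via the effective-medium forward map plus additive
#' index noise, truncation to the detection band, and Bernoulli
#' subsampling of the detected population.
#'
#' @param d_min_um,d_max_um detection band (default 0.5-10 um, inclusive).
#' @param sigma_d_rel relative diameter noise.
#' @param sigma_n additive refractive-index noise.
#' @param phi_dense mean dense-phase protein volume fraction.
#' @param phi_spread droplet-to-droplet sd of the volume fraction.
#' @param mixing a [mixing_params()] object (forward map).
#' @param subsample_fraction Bernoulli detection probability in (0, 1].
#' @return object of class \code{"measurement_model"}.
#' @export
measurement_model <- function(d_min_um = 0.5, d_max_um = 10,
                              sigma_d_rel = 0.02, sigma_n = 1e-4,
                              phi_dense = 0.05, phi_spread = 0,
                              mixing = mixing_params(),
                              subsample_fraction = 1) {
  if (subsample_fraction <= 0 || subsample_fraction > 1) {
    stop("subsample_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (sigma_d_rel < 0 || sigma_n < 0 || phi_spread < 0) {
    stop("noise scales must be non-negative", call. = FALSE)
  }
  stopifnot(inherits(mixing, "mixing_params"))
  structure(list(d_min_um = d_min_um, d_max_um = d_max_um,
                 sigma_d_rel = sigma_d_rel, sigma_n = sigma_n,
                 phi_dense = phi_dense, phi_spread = phi_spread,
                 mixing = mixing,
                 subsample_fraction = subsample_fraction),
            class = "measurement_model")
}

#' Apply the measurement model to a ground-truth dataset
#'
#' @param truth a \code{condensate_timeseries} of ground-truth snapshots.
#' @param mm a [measurement_model()].
#' @param seed integer seed.
#' @return a \code{condensate_timeseries} of measured snapshots; the
#'   sampled volume is scaled by the subsample fraction so number-density
#'   estimates stay unbiased.
#' @export
apply_measurement_model <- function(truth, mm = measurement_model(),
                                    seed = NULL) {
  stopifnot(inherits(truth, "condensate_timeseries"),
            inherits(mm, "measurement_model"))
  if (!is.null(seed)) set.seed(seed)
  snaps <- lapply(truth$snapshots, function(s) {
    d <- s$records$diameter_um
    n <- length(d)
    dd <- if (mm$sigma_d_rel > 0) {
      d * pmax(1 + mm$sigma_d_rel * stats::rnorm(n), 0.01)
    } else d
    phi <- if (mm$phi_spread > 0) {
      pmin(1, pmax(0, stats::rnorm(n, mm$phi_dense, mm$phi_spread)))
    } else rep(mm$phi_dense, n)
    np <- index_from_volume_fraction(phi, mm$mixing)
    if (mm$sigma_n > 0) np <- np + stats::rnorm(n, 0, mm$sigma_n)
    np <- pmax(np, mm$mixing$medium_index * (1 + 1e-9))
    keep <- dd >= mm$d_min_um & dd <= mm$d_max_um
    if (mm$subsample_fraction < 1) {
      keep <- keep & (stats::runif(n) < mm$subsample_fraction)
    }
    rec <- data.frame(replicate_id = s$records$replicate_id[keep],
                      time_s = s$records$time_s[keep],
                      droplet_id = s$records$droplet_id[keep],
                      diameter_um = dd[keep],
                      refractive_index = np[keep],
                      z_um = s$records$z_um[keep])
    population_snapshot(droplet_records(rec),
                        sampled_volume_mL =
                          s$sampled_volume_mL * mm$subsample_fraction,
                        medium_index = mm$mixing$medium_index,
                        wavelength_nm = s$wavelength_nm,
                        time_bin = s$time_bin)
  })
  out <- condensate_timeseries(snaps,
                               label = paste(truth$label, "(measured)"))
  attr(out, "measurement_model") <- mm
  attr(out, "config") <- attr(truth, "config")
  out
}

#' Two-component disequilibrium mixture population
#'
#' Generates the skewed population signature of a condensate system far
#' from equilibrium: one component of large, dilute (low-index) droplets
#' and one of small, dense (high-index) droplets, producing a strong
#' size-composition anticorrelation for the distance-correlation metric
#' to detect. Weight 0 or 1 degenerates to a single component.
#'
#' @param n total droplet count.
#' @param weight fraction of droplets in component A, in \[0, 1\].
#' @param comp_a,comp_b named lists \code{mean_d, sd_d, mean_phi, sd_phi}.
#' @param mixing a [mixing_params()] forward map.
#' @param sampled_volume_mL snapshot metadata.
#' @param seed integer seed.
#' @return a \code{population_snapshot} with a \code{component} attribute
#'   carrying the ground-truth labels.
#' @export
generate_disequilibrium_mixture <- function(
    n = 1000, weight = 0.5,
    comp_a = list(mean_d = 4, sd_d = 0.8, mean_phi = 0.03, sd_phi = 0.004),
    comp_b = list(mean_d = 1, sd_d = 0.2, mean_phi = 0.12, sd_phi = 0.008),
    mixing = mixing_params(),
    sampled_volume_mL = 1e-4,
    seed = NULL) {
  if (weight < 0 || weight > 1) {
    stop("weight must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  in_a <- stats::runif(n) < weight
  draw <- function(spec, m) {
    d <- pmax(stats::rnorm(m, spec$mean_d, spec$sd_d), 0.05)
    phi <- pmin(1, pmax(0, stats::rnorm(m, spec$mean_phi, spec$sd_phi)))
    list(d = d, np = index_from_volume_fraction(phi, mixing))
  }
  a <- draw(comp_a, sum(in_a)); b <- draw(comp_b, sum(!in_a))
  d <- numeric(n); np <- numeric(n)
  d[in_a] <- a$d; d[!in_a] <- b$d
  np[in_a] <- a$np; np[!in_a] <- b$np
  rec <- data.frame(replicate_id = "mixture", time_s = 0,
                    droplet_id = seq_len(n), diameter_um = d,
                    refractive_index = np, z_um = NA_real_)
  out <- population_snapshot(droplet_records(rec),
                             sampled_volume_mL = sampled_volume_mL,
                             medium_index = mixing$medium_index)
  attr(out, "component") <- ifelse(in_a, "A", "B")
  out
}

#' Synthetic single-molecule localization fixture
#'
#' Gaussian clusters of localizations plus a uniform background, with the
#' ground-truth cluster labels retained so clustering output can be scored
#' against construction.
#'
#' @param n_clusters number of clusters.
#' @param cluster_sd_nm Gaussian cluster radius (sd), nanometers.
#' @param points_per_cluster localizations per cluster.
#' @param noise_fraction fraction of total points drawn uniformly over the
#'   field.
#' @param field_nm square field side, nanometers; cluster centers are
#'   placed on a jittered grid so they stay well separated.
#' @param n_frames localizations get random frame indexes in
#'   \code{0:(n_frames-1)}.
#' @param seed integer seed.
#' @return object of class \code{"localization_set"}: data.frame
#'   \code{points} (x_nm, y_nm, frame), \code{true_label} (0 = background),
#'   \code{centers}.
#' @export
generate_smlm_fixture <- function(n_clusters = 5, cluster_sd_nm = 20,
                                  points_per_cluster = 200,
                                  noise_fraction = 0.1,
                                  field_nm = 5000, n_frames = 1000,
                                  seed = NULL) {
  if (n_clusters < 1 || points_per_cluster < 1 || field_nm <= 0) {
    stop("dimensions must be positive", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  side <- ceiling(sqrt(n_clusters))
  cell <- field_nm / side
  grid <- expand.grid(ix = seq_len(side) - 0.5, iy = seq_len(side) - 0.5)
  grid <- grid[seq_len(n_clusters), ]
  centers <- cbind(x = grid$ix * cell + stats::runif(n_clusters, -0.1, 0.1) * cell,
                   y = grid$iy * cell + stats::runif(n_clusters, -0.1, 0.1) * cell)
  n_sig <- n_clusters * points_per_cluster
  n_noise <- round(noise_fraction * n_sig / max(1e-12, 1 - noise_fraction))
  lab <- rep(seq_len(n_clusters), each = points_per_cluster)
  x <- stats::rnorm(n_sig, centers[lab, "x"], cluster_sd_nm)
  y <- stats::rnorm(n_sig, centers[lab, "y"], cluster_sd_nm)
  if (n_noise > 0) {
    x <- c(x, stats::runif(n_noise, 0, field_nm))
    y <- c(y, stats::runif(n_noise, 0, field_nm))
    lab <- c(lab, rep(0L, n_noise))
  }
  frame <- sample.int(n_frames, length(x), replace = TRUE) - 1L
  structure(list(points = data.frame(x_nm = x, y_nm = y, frame = frame),
                 true_label = lab,
                 centers = centers,
                 field_nm = field_nm),
            class = "localization_set")
}

#' Synthetic fluctuating image stack
#'
#' A static spatial intensity pattern plus, inside a mobile region, a
#' temporally white fluctuating component (fast, unresolvable molecular
#' motion) and optionally a slow AR(1)-correlated component (motion
#' persisting across frames). The lag-1 temporal correlation of a mobile
#' pixel is then approximately
#' \eqn{\rho\,\sigma_{slow}^2/(\sigma_{slow}^2 + \sigma_{fast}^2)}, so
#' raising the fast (mobile) variance monotonically lowers the
#' correlation — the knob used to emulate increasingly dynamic
#' condensate interiors. Ground-truth maps are retained for scoring.
#'
#' @param width,height frame size, pixels.
#' @param n_frames number of frames.
#' @param static_map base intensity image (matrix height x width);
#'   default a smooth blob pattern.
#' @param mobile_mask logical matrix marking pixels with temporal
#'   fluctuations; default the right half of the field.
#' @param fluct_sd standard deviation of the white (fast) fluctuations.
#' @param slow_sd standard deviation of the AR(1) slow component
#'   (default 0: none).
#' @param slow_ar lag-1 autocorrelation of the slow component.
#' @param frame_interval_ms acquisition interval, default 20 ms.
#' @param seed integer seed.
#' @return object of class \code{"image_stack"}: \code{data}
#'   (array height x width x frames), \code{frame_interval_ms},
#'   \code{static_map}, \code{mobile_mask}.
#' @export
generate_stack_fixture <- function(width = 32, height = 32, n_frames = 200,
                                   static_map = NULL, mobile_mask = NULL,
                                   fluct_sd = 1, slow_sd = 0, slow_ar = 0.9,
                                   frame_interval_ms = 20,
                                   seed = NULL) {
  if (width < 1 || height < 1 || n_frames < 2) {
    stop("dimensions must be positive (and n_frames >= 2)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(static_map)) {
    xx <- matrix(seq_len(width), height, width, byrow = TRUE)
    yy <- matrix(seq_len(height), height, width)
    static_map <- 50 + 30 * exp(-((xx - width / 3)^2 +
                                    (yy - height / 2)^2) / (width / 3)^2)
  }
  if (is.null(mobile_mask)) {
    mobile_mask <- matrix(FALSE, height, width)
    mobile_mask[, seq(ceiling(width / 2) + 1L, width)] <- TRUE
  }
  stopifnot(all(dim(static_map) == c(height, width)),
            all(dim(mobile_mask) == c(height, width)))
  data <- array(rep(static_map, n_frames), dim = c(height, width, n_frames))
  nm <- sum(mobile_mask)
  if (nm > 0 && (fluct_sd > 0 || slow_sd > 0)) {
    slow <- if (slow_sd > 0) {
      stats::rnorm(nm, 0, slow_sd)
    } else numeric(nm)
    innov_sd <- slow_sd * sqrt(1 - slow_ar^2)
    for (f in seq_len(n_frames)) {
      frame <- data[, , f]
      add <- slow
      if (fluct_sd > 0) add <- add + stats::rnorm(nm, 0, fluct_sd)
      frame[mobile_mask] <- frame[mobile_mask] + add
      data[, , f] <- frame
      if (slow_sd > 0) {
        slow <- slow_ar * slow + stats::rnorm(nm, 0, innov_sd)
      }
    }
  }
  structure(list(data = data,
                 frame_interval_ms = frame_interval_ms,
                 static_map = static_map,
                 mobile_mask = mobile_mask),
            class = "image_stack")
}
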