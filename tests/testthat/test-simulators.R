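test_that("coagulation conserves volume with df = 3 and mass generally", {
  cfg <- sim_config(n_seeds = 800, df_merge = 3, t_end_s = 1000,
                    kernel_prefactor = 5e-4, rng_seed = 2)
  ts <- simulate_coagulation(cfg)
  v <- vapply(ts$snapshots, function(s) sum(s$records$diameter_um^3),
              numeric(1))
  expect_lt(diff(range(v)) / max(v), 1e-9)

  # generalized conservation n * <d^df> for the fractal rule with barrier
  cfg2 <- sim_config(n_seeds = 800, df_merge = 2, barrier_scale_kT = 0.2,
                     t_end_s = 1000, kernel_prefactor = 5e-6, rng_seed = 3)
  ts2 <- simulate_coagulation(cfg2)
  m <- vapply(ts2$snapshots, function(s) sum(s$records$diameter_um^2),
              numeric(1))
  expect_lt(diff(range(m)) / max(m), 1e-9)
})

test_that("a very large barrier freezes the population", {
  cfg <- sim_config(n_seeds = 200, barrier_scale_kT = 60, t_end_s = 500,
                    kernel_prefactor = 1e-3, rng_seed = 4)
  ts <- simulate_coagulation(cfg)
  expect_equal(attr(ts, "n_merges"), 0L)
  n <- vapply(ts$snapshots, function(s) nrow(s$records), integer(1))
  expect_true(all(n == 200L))
})

test_that("coagulation runs are bit-reproducible and nucleation adds droplets", {
  cfg <- sim_config(n_seeds = 300, t_end_s = 500, kernel_prefactor = 2e-4,
                    rng_seed = 11)
  a <- simulate_coagulation(cfg)
  b <- simulate_coagulation(cfg)
  expect_identical(lapply(a$snapshots, function(s) s$records$diameter_um),
                   lapply(b$snapshots, function(s) s$records$diameter_um))

  cfg_nuc <- sim_config(n_seeds = 50, t_end_s = 200, kernel_prefactor = 0,
                        nucleation_rate_per_s = 1, t_nuc_stop_s = 100,
                        rng_seed = 12)
  ts <- simulate_coagulation(cfg_nuc)
  n <- vapply(ts$snapshots, function(s) nrow(s$records), integer(1))
  expect_gt(max(n), 50)
  # nucleation stops: count stable between stop time and the end
  late <- n[cfg_nuc$snapshot_times_s > 100]
  expect_true(all(diff(late) == 0))
})

test_that("LSW ripening conserves volume and stalls without polydispersity", {
  tr <- simulate_lsw(n_droplets = 2000, t_end_s = 100, rng_seed = 5)
  expect_lt(tr$volume_drift, 1e-9)
  expect_lt(nrow(tr$series) - sum(tr$series$n > 0), 1)

  expect_warning(mono <- simulate_lsw(n_droplets = 200, sd_frac = 0,
                                      t_end_s = 50, rng_seed = 6),
                 "monodisperse")
  expect_lt(diff(range(mono$series$mean_radius_um)), 1e-12)
})

test_that("model trajectory sampler round-trips both growth laws", {
  tr <- sample_model_trajectory("power_law",
                                list(prefactor = 0.6, beta = 0.16),
                                noise_rel = 0)
  expect_equal(fit_power_law(tr$times, tr$mean_diams)$beta, 0.16,
               tolerance = 1e-10)
  tr2 <- sample_model_trajectory("self_regulated",
                                 list(d0 = 1, t0 = 300, df = 2),
                                 noise_rel = 0, t_range = c(400, 7200))
  fit <- fit_self_regulated(tr2$times, tr2$mean_diams)
  expect_equal(fit$d0_um, 1, tolerance = 1e-6)
  expect_equal(fit$t0_s, 300, tolerance = 1e-4)
  expect_error(sample_model_trajectory("power_law", list(prefactor = -1)),
               "positive")
})

test_that("measurement model reproduces truth in the noiseless limit", {
  cfg <- sim_config(n_seeds = 100, t_end_s = 100, kernel_prefactor = 1e-4,
                    rng_seed = 7)
  truth <- simulate_coagulation(cfg)
  mm <- measurement_model(sigma_d_rel = 0, sigma_n = 0, phi_dense = 0.05,
                          phi_spread = 0, d_min_um = 1e-6, d_max_um = 1e6)
  meas <- apply_measurement_model(truth, mm, seed = 1)
  expect_equal(meas$snapshots[[1]]$records$diameter_um,
               truth$snapshots[[1]]$records$diameter_um)
  expect_equal(unique(meas$snapshots[[1]]$records$refractive_index),
               index_from_volume_fraction(0.05, mm$mixing))
})

test_that("detection-band truncation biases the measured mean upward", {
  # truth containing sub-band droplets: measured mean must exceed true mean
  d_true <- c(runif(300, 0.2, 0.45), runif(300, 0.6, 3))
  snaps <- list(make_snapshot(d_true))
  snaps[[1]]$records$refractive_index <- NA_real_
  truth <- condensate_timeseries(snaps, "truncation")
  mm <- measurement_model(sigma_d_rel = 0, sigma_n = 0, phi_spread = 0)
  meas <- apply_measurement_model(truth, mm, seed = 2)
  expect_lt(max(meas$snapshots[[1]]$records$diameter_um), 10 + 1e-9)
  expect_gt(min(meas$snapshots[[1]]$records$diameter_um), 0.5 - 1e-9)
  expect_gt(population_stats(meas$snapshots[[1]])$mean_d, mean(d_true))
})

test_that("uniform composition yields uncorrelated size and index", {
  cfg <- sim_config(n_seeds = 600, t_end_s = 400, kernel_prefactor = 2e-4,
                    rng_seed = 8)
  truth <- simulate_coagulation(cfg)
  mm <- measurement_model(sigma_d_rel = 0.02, sigma_n = 1e-4,
                          phi_dense = 0.05, phi_spread = 0)
  meas <- apply_measurement_model(truth, mm, seed = 3)
  s <- meas$snapshots[[1]]
  # independence null at this sample size
  set.seed(30)
  n <- nrow(s$records)
  null <- replicate(60, distance_correlation(
    sample(s$records$diameter_um), s$records$refractive_index))
  v <- distance_correlation(s$records$refractive_index,
                            s$records$diameter_um)
  expect_lt(v, quantile(null, 0.99) * 1.5)
})

test_that("disequilibrium mixture produces detectable anticorrelation", {
  # null distribution for independent populations of the same size
  set.seed(40)
  null <- replicate(60, {
    distance_correlation(runif(1000, 1, 5), rnorm(1000, 1.36, 0.003))
  })
  mix <- generate_disequilibrium_mixture(n = 1000, weight = 0.5, seed = 41)
  v <- distance_correlation(mix$records$refractive_index,
                            mix$records$diameter_um)
  expect_gt(v, quantile(null, 0.99))

  # single component at weight 0
  single <- generate_disequilibrium_mixture(n = 500, weight = 0, seed = 42)
  expect_true(all(attr(single, "component") == "B"))

  # identical composition across components: no coupling signal
  same_phi <- generate_disequilibrium_mixture(
    n = 1000, weight = 0.5,
    comp_a = list(mean_d = 4, sd_d = 0.8, mean_phi = 0.05, sd_phi = 0.004),
    comp_b = list(mean_d = 1, sd_d = 0.2, mean_phi = 0.05, sd_phi = 0.004),
    seed = 43)
  v2 <- distance_correlation(same_phi$records$refractive_index,
                             same_phi$records$diameter_um)
  expect_lt(v2, quantile(null, 0.999) * 2)
  expect_error(generate_disequilibrium_mixture(weight = 1.5), "weight")
})

test_that("fixture generators are reproducible and labelled", {
  a <- generate_smlm_fixture(seed = 1)
  b <- generate_smlm_fixture(seed = 1)
  expect_identical(a$points, b$points)
  expect_equal(length(a$true_label), nrow(a$points))

  s1 <- generate_stack_fixture(seed = 2)
  s2 <- generate_stack_fixture(seed = 2)
  expect_identical(s1$data, s2$data)
  expect_error(generate_stack_fixture(width = 0), "positive")
  expect_error(generate_smlm_fixture(n_clusters = 0), "positive")
})

test_that("coagulation-simulator output recovers the merge-rule fractal dimension", {
  fx <- jsonlite::read_json(
    system.file("extdata", "gelpoint_fixture.json", package = "condkit"),
    simplifyVector = TRUE)
  cfg <- sim_config(n_seeds = fx$n_seeds, df_merge = fx$df_merge,
                    alpha = fx$alpha, barrier_scale_kT = fx$barrier_scale_kT,
                    kernel_prefactor = fx$kernel_prefactor,
                    t_end_s = fx$t_end_s,
                    snapshot_times_s = exp(seq(log(fx$snapshot_t_min_s),
                                               log(fx$t_end_s),
                                               length.out = fx$n_snapshots)),
                    sampled_volume_mL = fx$sampled_volume_mL, rng_seed = 123)
  ts <- simulate_coagulation(cfg)
  n <- vapply(ts$snapshots, function(s) nrow(s$records), integer(1))
  dens <- n / cfg$sampled_volume_mL
  md <- vapply(ts$snapshots, function(s) {
    population_stats(filter_detection_band(s, fx$detection_band_um[1],
                                           fx$detection_band_um[2]))$mean_d
  }, numeric(1))
  keep <- dens <= max(dens) * fx$coarsening_density_fraction
  fit <- fit_mass_fractal(dens[keep], md[keep])
  # direct conservation oracle: n * <d^df> constant => slope of
  # log <d> vs log(n0/n) is 1/df up to shape drift
  expect_lt(abs(fit$df - fx$df_merge), 0.2)
  m2 <- vapply(ts$snapshots, function(s) sum(s$records$diameter_um^2),
               numeric(1))
  expect_lt(diff(range(m2)) / max(m2), 1e-9)
})
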