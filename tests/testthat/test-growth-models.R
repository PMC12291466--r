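test_that("power-law fitter recovers exact and degenerate exponents", {
  t <- seq(60, 3600, by = 180)
  fit <- fit_power_law(t, 2 * t^0.16)
  expect_equal(fit$beta, 0.16, tolerance = 1e-10)
  expect_lt(fit$beta_se, 1e-10)
  expect_equal(fit$prefactor, 2, tolerance = 1e-8)

  flat <- fit_power_law(t, rep(3, length(t)))
  expect_equal(flat$beta, 0, tolerance = 1e-12)

  expect_error(fit_power_law(c(-1, 2, 3), c(1, 2, 3)), "positive")
  expect_error(fit_power_law(c(1, 2), c(1, 2)), "at least 3")
})

test_that("power-law fit under noise matches a generic curve-fit oracle", {
  tr <- sample_model_trajectory("power_law",
                                list(prefactor = 1, beta = 0.25),
                                noise_rel = 0.02, n_times = 20, seed = 31)
  fit <- fit_power_law(tr$times, tr$mean_diams, tr$ses)
  expect_lt(abs(fit$beta - 0.25), 3 * fit$beta_se)
  # independent oracle: direct nonlinear fit of a * t^b on the linear scale
  oracle <- stats::nls(d ~ a * t^b,
                       data = data.frame(t = tr$times, d = tr$mean_diams),
                       start = list(a = 1, b = 0.3))
  expect_equal(fit$beta, unname(coef(oracle)["b"]), tolerance = 0.02)
})

test_that("growth exponent is invariant under time-unit rescaling", {
  tr <- sample_model_trajectory("power_law",
                                list(prefactor = 0.6, beta = 0.16),
                                noise_rel = 0.02, seed = 5)
  b1 <- fit_power_law(tr$times, tr$mean_diams, tr$ses)$beta
  b2 <- fit_power_law(tr$times / 60, tr$mean_diams, tr$ses)$beta
  expect_equal(b1, b2, tolerance = 1e-10)
})

test_that("Smoluchowski width matches gamma-function values and its identity", {
  expect_equal(smoluchowski_width(0), sqrt(pi) / 2, tolerance = 1e-12)
  expect_equal(smoluchowski_width(1), 3 * sqrt(pi) / 4, tolerance = 1e-12)
  for (a in c(-0.5, 0, 1, 1.94, 3.8)) {
    expect_equal(smoluchowski_width(a),
                 exp(lgamma(a + 1.5) - lgamma(a + 1)),
                 tolerance = 1e-12)
  }
  expect_error(smoluchowski_width(-1), "alpha")
})

test_that("scaled Smoluchowski density evaluates, normalizes and has unit mean", {
  W <- sqrt(pi) / 2
  expect_equal(smoluchowski_pdf(1, 1, 0), 2 * W^2 * exp(-W^2),
               tolerance = 1e-12)
  for (a in c(0, 1.94, 3.8)) {
    norm <- integrate(function(d) smoluchowski_pdf(d, 1, a), 0, Inf,
                      rel.tol = 1e-10)$value
    m1 <- integrate(function(d) d * smoluchowski_pdf(d, 1, a), 0, Inf,
                    rel.tol = 1e-10)$value
    expect_equal(norm, 1, tolerance = 1e-8)
    expect_equal(m1, 1, tolerance = 1e-8)
  }
  # scale equivariance: density over d at mean mu is the unit-mean density
  # of d/mu divided by mu
  expect_equal(smoluchowski_pdf(3, 2, 1.5),
               smoluchowski_pdf(1.5, 1, 1.5) / 2, tolerance = 1e-12)
})

test_that("normalization and unit mean hold across the alpha grid", {
  for (a in c(-0.9, -0.5, 0.25, 1, 2.5, 4, 6)) {
    norm <- integrate(function(d) smoluchowski_pdf(d, 1, a), 0, Inf,
                      rel.tol = 1e-10)$value
    m1 <- integrate(function(d) d * smoluchowski_pdf(d, 1, a), 0, Inf,
                    rel.tol = 1e-10)$value
    expect_equal(norm, 1, tolerance = 1e-8)
    expect_equal(m1, 1, tolerance = 1e-8)
  }
})

test_that("Smoluchowski sampler matches its own density", {
  d <- sample_smoluchowski(1e5, mean_d = 2, alpha = 1, seed = 21)
  expect_lt(abs(mean(d) - 2), 3 * sd(d) / sqrt(1e5))
  expect_identical(sample_smoluchowski(1000, 2, 1, seed = 9),
                   sample_smoluchowski(1000, 2, 1, seed = 9))
  # KS against the alpha = 0 closed-form CDF 1 - exp(-(W d / mu)^2)
  d0 <- sample_smoluchowski(1e5, 1, 0, seed = 33)
  W <- smoluchowski_width(0)
  ks <- suppressWarnings(
    stats::ks.test(d0, function(q) 1 - exp(-(W * q)^2)))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(1e5))
})

test_that("alpha MLE recovers the generating exponent", {
  for (truth in c(1, 1.94, 3.8)) {
    d <- sample_smoluchowski(1e5, 1, truth, seed = 100 + round(10 * truth))
    fit <- fit_smoluchowski_alpha(d)
    expect_lt(abs(fit$alpha - truth), 3 * fit$alpha_se)
    # optimality of the profile likelihood at the optimum
    ll <- condkit:::smoluchowski_loglik
    expect_gte(fit$loglik, ll(fit$alpha + 0.5, d, mean(d)))
    expect_gte(fit$loglik, ll(fit$alpha - 0.5, d, mean(d)))
  }
  expect_error(fit_smoluchowski_alpha(rep(1, 100)), "degenerate")
  expect_error(fit_smoluchowski_alpha(runif(10)), "at least 50")
})

test_that("the beta-alpha relation is an exact involution", {
  expect_equal(beta_alpha_relation(1, "beta_from_alpha"), 0.25)
  expect_equal(beta_alpha_relation(0.5, "alpha_from_beta"), 0)
  expect_equal(beta_alpha_relation(0.16, "alpha_from_beta"), 2.125)
  alphas <- seq(-0.9, 6, by = 0.37)
  back <- beta_alpha_relation(
    beta_alpha_relation(alphas, "beta_from_alpha"), "alpha_from_beta")
  expect_equal(back, alphas, tolerance = 1e-14)
  expect_error(beta_alpha_relation(-1.2, "beta_from_alpha"), "alpha")
  expect_error(beta_alpha_relation(0, "alpha_from_beta"), "beta")
})

test_that("scaling collapse separates shared-shape from different-shape data", {
  # Monte-Carlo threshold for same-distribution divergence at this sample
  # size: pairs of same-alpha snapshots, fixed seed
  n_per <- 400
  set.seed(77)
  null_jsd <- replicate(40, {
    ds <- make_scaling_dataset(c(1, 2), c(1, 1.5), alpha = 1,
                               n_per = n_per, seed = sample.int(1e6, 1))
    scaling_collapse(ds, bins = 30)$max_jsd
  })
  thr <- quantile(null_jsd, 0.99)

  same <- make_scaling_dataset(c(1, 2, 3), c(1, 1.6, 2.2), alpha = 1,
                               n_per = n_per, seed = 11)
  expect_lt(scaling_collapse(same, bins = 30)$max_jsd, thr * 1.5)

  mixed_a <- make_scaling_dataset(1, 1, alpha = 1, n_per = n_per, seed = 12)
  mixed_b <- make_scaling_dataset(2, 1.5, alpha = 3.8, n_per = n_per,
                                  seed = 13)
  mixed <- condensate_timeseries(c(mixed_a$snapshots, mixed_b$snapshots),
                                 "mixed")
  expect_gt(scaling_collapse(mixed, bins = 30)$max_jsd, thr)

  # identical diameters in two snapshots collapse exactly
  d <- sample_smoluchowski(500, 1, 1, seed = 5)
  s1 <- make_snapshot(d, times = 0)
  s2 <- make_snapshot(2 * d, times = 10)
  ident <- condensate_timeseries(list(s1, s2), "ident")
  expect_equal(scaling_collapse(ident, bins = 30)$max_jsd, 0,
               tolerance = 1e-12)
})

test_that("self-regulated fit recovers parameters and anchors d0 at t0", {
  tt <- exp(seq(log(400), log(7200), length.out = 12))
  dd <- self_regulated_mean(tt, d0 = 1, t0 = 300, df = 2)
  fit <- fit_self_regulated(tt, dd)
  expect_equal(fit$d0_um, 1, tolerance = 1e-6)
  expect_equal(fit$t0_s, 300, tolerance = 1e-4)
  expect_equal(self_regulated_mean(300, fit$d0_um, fit$t0_s, 2), fit$d0_um)

  # model value at t = t0 is d0 for any parameters (the +e anchor)
  expect_equal(self_regulated_mean(123, 2.5, 123, 3), 2.5)
  expect_equal(self_regulated_mean(50, 1.2, 50, 2, form = "inner_df"), 1.2)

  tr <- sample_model_trajectory("self_regulated",
                                list(d0 = 1, t0 = 300, df = 2),
                                noise_rel = 0.02, n_times = 16,
                                t_range = c(400, 7200), seed = 8)
  nf <- fit_self_regulated(tr$times, tr$mean_diams, tr$ses)
  expect_lt(abs(nf$d0_um - 1), 3 * nf$d0_se)
  expect_lt(abs(nf$t0_s - 300), 3 * nf$t0_se)
})

test_that("self-regulated fit honours the alternative model form", {
  tt <- exp(seq(log(400), log(7200), length.out = 10))
  dd <- self_regulated_mean(tt, 1.5, 200, 2, form = "inner_df")
  fit <- fit_self_regulated(tt, dd, form = "inner_df")
  expect_equal(fit$d0_um, 1.5, tolerance = 1e-6)
  expect_equal(fit$t0_s, 200, tolerance = 1e-4)
})

test_that("mass-fractal fit inverts the diameter-density relation exactly", {
  n0 <- 1e7
  dens <- n0 / exp(seq(0, 3, length.out = 8))
  for (truth in c(2, 3)) {
    diam <- 1.2 * (n0 / dens)^(1 / truth)
    fit <- fit_mass_fractal(dens, diam)
    expect_equal(fit$df, truth, tolerance = 1e-10)
    expect_equal(fit$n0_per_mL, n0)
  }
  expect_warning(fit_mass_fractal(c(1e7, 2e7, 5e6), c(1, 1.1, 1.3)),
                 "monoton")
  expect_error(fit_mass_fractal(dens, rev(1.2 * (n0 / dens)^(1 / 2))),
               "slope")
})

test_that("model comparison ranks the generating mechanism first", {
  tt <- exp(seq(log(400), log(7200), length.out = 10))
  # self-regulated truth
  means_sr <- self_regulated_mean(tt, 1, 300, 2)
  set.seed(61)
  snaps <- lapply(seq_along(tt), function(i) {
    make_snapshot(pmax(rnorm(300, means_sr[i], 0.02 * means_sr[i]), 0.6),
                  times = tt[i])
  })
  ds <- condensate_timeseries(snaps, "sr")
  cmp <- compare_growth_models(ds, band = NULL)
  expect_equal(cmp$ranking[1], "self_regulated")

  # exact 1/3 power law: LSW reference not rejected
  means_lsw <- 0.2 * tt^(1 / 3)
  set.seed(62)
  snaps <- lapply(seq_along(tt), function(i) {
    make_snapshot(pmax(rnorm(300, means_lsw[i], 0.02 * means_lsw[i]), 0.2),
                  times = tt[i])
  })
  cmp2 <- compare_growth_models(condensate_timeseries(snaps, "lsw"),
                                band = NULL)
  expect_lt(abs(cmp2$z_beta_vs_lsw), 2)
  expect_false(cmp2$lsw_rejected)

  # slow growth: LSW strongly rejected
  means_slow <- 0.6 * tt^0.16
  set.seed(63)
  snaps <- lapply(seq_along(tt), function(i) {
    make_snapshot(pmax(rnorm(300, means_slow[i], 0.02 * means_slow[i]), 0.2),
                  times = tt[i])
  })
  cmp3 <- compare_growth_models(condensate_timeseries(snaps, "slow"),
                                band = NULL)
  expect_gt(abs(cmp3$z_beta_vs_lsw), 10)
  expect_true(cmp3$lsw_rejected)
})
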