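test_that("sampling correction reconstructs cumulative permeation", {
  geo <- cell_geometry()
  proto <- experiment_protocol(noise_cv = 0, sample_volume = 0.2)

  # zero sample volume: Q = C V / A
  proto0 <- experiment_protocol(noise_cv = 0, sample_volume = 0)
  cc <- c(seq_len(13), 14) / 100
  q0 <- cumulative_permeated(cc, proto0, geo)
  expect_equal(q0$q_mg_per_cm2, cc * 12 / 0.636)
  expect_equal(cumulative_permeated(rep(0, 14), proto, geo)$q_mg_per_cm2,
               rep(0, 14))
  expect_error(cumulative_permeated(c(-1, cc[-1]), proto, geo), "non-negative")

  # mass-accounting identity on a simulated sampled run: the corrected
  # cumulative amount equals the dose minus what remains in donor and skin
  cfg <- make_case_config("diclofenac_RT")
  disc <- study_disc()
  run <- franzcell:::simulate_with_sampling(cfg$layers, cfg$interfaces,
                                            cfg$geometry, disc,
                                            proto$sampling_times, 0.2)
  q_corr <- cumulative_permeated(run$observed, proto, geo)
  m_end <- layer_amounts(run$final, 48)
  expect_equal(tail(q_corr$q_mg_per_cm2, 1),
               (5 - m_end[["donor"]] - m_end[["skin"]]) / 0.636,
               tolerance = 1e-6)

  # removal/replacement perturbs the closed-cell trajectory only mildly
  # (each draw dilutes the receptor by ~1.7%)
  sim <- simulate_cell(cfg$layers, cfg$interfaces, cfg$geometry, disc,
                       output_times = proto$sampling_times)
  q_ref <- release_curve(sim)$concentration_mg_per_cm3 * 12 / 0.636
  expect_equal(q_corr$q_mg_per_cm2, q_ref, tolerance = 0.02)
})

test_that("lag-time regression recovers the x-intercept", {
  # exact line Q = 2 (t - 3)
  tt <- seq(9, 20, by = 1)
  lt <- estimate_lag_time(data.frame(time_h = tt, q_mg_per_cm2 = 2 * (tt - 3)))
  expect_equal(lt$lag_time, 3, tolerance = 1e-10)
  expect_equal(lt$steady_slope, 2, tolerance = 1e-10)

  # constant Q has no steady flux
  expect_error(estimate_lag_time(data.frame(time_h = tt, q_mg_per_cm2 = rep(1, 12))),
               "steady slope|quasi-linear")
  expect_error(estimate_lag_time(data.frame(time_h = 1:3, q_mg_per_cm2 = 1:3)),
               "at least")

  # sink-condition membrane: recovered lag within 10% of h^2 / (6 D)
  h <- 0.07; D <- 1.2e-3
  tt <- c(1, 2, 3, 4.5, 6, 8, 10, 12, 23, 26, 29, 32, 35, 48)
  q <- membrane_sink_q(tt, h, D, surface_concentration = 40)
  lt2 <- estimate_lag_time(data.frame(time_h = tt, q_mg_per_cm2 = q))
  expect_equal(lt2$lag_time, h^2 / (6 * D), tolerance = 0.1)
  expect_equal(diffusion_from_lag(lt2, h), D, tolerance = 0.1)
})

test_that("lag-time formula inverts as expected", {
  expect_equal(diffusion_from_lag(0.07^2 / (6 * 1.2e-3), 0.07), 1.2e-3)
  expect_equal(diffusion_from_lag(0.926, 0.1), 1.8e-3, tolerance = 0.01)
  # h^2 scaling: doubling thickness quadruples D at fixed lag
  expect_equal(diffusion_from_lag(2, 0.2) / diffusion_from_lag(2, 0.1), 4)
  expect_error(diffusion_from_lag(0, 0.1), "positive")
})

test_that("membrane sink series behaves like the classical solution", {
  h <- 0.1; D <- 5e-3
  tt <- seq(0, 40, by = 0.5)
  q <- membrane_sink_q(tt, h, D, surface_concentration = 2)
  expect_equal(q[1], 0)
  expect_true(all(diff(q) >= 0))
  # asymptote: Q ~ (D Cs / h) (t - h^2 / 6D) at large t
  asym <- (D * 2 / h) * (tt - h^2 / (6 * D))
  expect_equal(q[tt > 10], asym[tt > 10], tolerance = 1e-6)
})

test_that("P1 is recovered from a tape-strip total", {
  cfg <- make_case_config("diclofenac_32C")
  disc <- study_disc()
  # target generated with known P1 = 5 and the true remaining parameters
  sim <- simulate_cell(cfg$layers, cfg$interfaces, cfg$geometry, disc,
                       output_times = 48)
  target <- sum(strip_amounts_from_profile(sim, 48, 0.75e-4))
  p1 <- estimate_P1(target, cfg$layers, cfg$interfaces, cfg$geometry, 48,
                    disc = disc)
  expect_equal(as.numeric(p1), 5, tolerance = 0.02)

  # monotone in the strip total on the rising branch
  p1s <- vapply(c(0.7, 0.85, 1) * target, function(tgt) {
    as.numeric(estimate_P1(tgt, cfg$layers, cfg$interfaces, cfg$geometry, 48,
                           disc = disc))
  }, numeric(1))
  expect_true(all(diff(p1s) > 0))

  expect_error(estimate_P1(0, cfg$layers, cfg$interfaces, cfg$geometry, 48),
               "positive")
  expect_error(estimate_P1(100, cfg$layers, cfg$interfaces, cfg$geometry, 48,
                           disc = disc), "outside the range")
})

test_that("interface-parameter fit recovers truth from a noiseless curve", {
  cfg <- make_case_config("diclofenac_RT")
  disc <- study_disc()
  expn <- generate_experiment(cfg, experiment_protocol(noise_cv = 0, seed = 11),
                              disc = disc)
  fit <- fit_interface_params(expn$release, cfg$layers, cfg$interfaces,
                              cfg$geometry, disc = disc, n_starts = 3)
  expect_true(fit$converged)
  expect_equal(fit$P2, 25, tolerance = 0.05)
  expect_equal(fit$K1, 0.08, tolerance = 0.05)
  expect_equal(fit$K2, 0.04, tolerance = 0.05)

  # starting from the truth, the objective is (numerically) zero immediately
  fit0 <- fit_interface_params(expn$release, cfg$layers, cfg$interfaces,
                               cfg$geometry, disc = disc, n_starts = 1,
                               init = c(25, 0.08, 0.04))
  expect_lt(fit0$objective, 1e-10)

  expect_error(fit_interface_params(expn$release[expn$release$time_h < 4, ],
                                    cfg$layers, cfg$interfaces, cfg$geometry),
               "at least 6")
})

test_that("calibrate_case requires a diffusivity source and validates inputs", {
  rel <- data.frame(time_h = c(1, 2, 3, 4, 5, 6),
                    concentration_mg_per_ml = seq(0.01, 0.06, by = 0.01))
  expect_error(calibrate_case(rel, 0.03, 0.07, cell_geometry()),
               "supply `D`")
})
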