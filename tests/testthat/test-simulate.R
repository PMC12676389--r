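test_that("configuration validation names the offending field", {
  expect_error(sim_config(state_occupancies = c(0.4, 0.4)), "sum to 1")
  expect_error(sim_config(state_means = c(0.5, 1.2)), "state_means")
  expect_error(sim_config(leakage_alpha = 1.2), "leakage_alpha")
  expect_error(sim_config(transition_rates = matrix(c(0, -1, 1, 0), 2, 2)),
               "transition_rates")
  expect_error(sim_config(gamma_range = c(2, 1)), "gamma_range")
  expect_error(sim_config(contaminant_fractions = c(donor_only = 0.8,
                                                    aggregate = 0.5)),
               "contaminant_fractions")
})

test_that("noise-free signal model honours the FRET and leakage arithmetic", {
  # symmetric case: E = 0.5, gamma = 1 -> both channels at I0/2 every frame
  cfg <- sim_config(n_frames_donor_exc = 50, state_means = 0.5,
                    state_occupancies = 1, gamma_range = c(1, 1),
                    leakage_alpha = 0, background_sigma = 0,
                    shot_noise = FALSE, donor_bleach_lifetime = 1e9,
                    acceptor_bleach_lifetime = 1e9, seed = 1)
  tr <- simulate_traces(cfg, 1)$traces[[1]]
  expect_equal(tr$donor, rep(500, 50))
  expect_equal(tr$acceptor, rep(500, 50))

  # zero transfer: raw acceptor is exactly alpha * donor
  cfg0 <- sim_config(n_frames_donor_exc = 50, state_means = 0,
                     state_occupancies = 1, gamma_range = c(1, 1),
                     leakage_alpha = 0.07, background_sigma = 0,
                     shot_noise = FALSE, donor_bleach_lifetime = 1e9,
                     acceptor_bleach_lifetime = 1e9, seed = 1)
  tr0 <- simulate_traces(cfg0, 1)$traces[[1]]
  expect_equal(tr0$donor, rep(1000, 50))
  expect_equal(tr0$acceptor, rep(70, 50))
})

test_that("signal conservation holds per frame under the gamma convention", {
  cfg <- sim_config(n_frames_donor_exc = 200, state_means = c(0.3, 0.8),
                    state_occupancies = c(0.5, 0.5),
                    transition_rates = matrix(c(0, 2, 2, 0), 2, 2),
                    gamma_range = c(0.5, 2.5), leakage_alpha = 0,
                    background_sigma = 0, shot_noise = FALSE,
                    donor_bleach_lifetime = 1e9,
                    acceptor_bleach_lifetime = 1e9, seed = 4)
  sim <- simulate_traces(cfg, 5)
  for (k in 1:5) {
    tr <- sim$traces[[k]]
    g <- sim$truth$gamma[k]
    expect_equal(tr$donor + tr$acceptor / g, rep(1000, 200), tolerance = 1e-12)
    # corrected estimator recovers the state mean exactly
    E <- tr$acceptor / (tr$acceptor + g * tr$donor)
    expect_equal(E, cfg$state_means[sim$state_paths[[k]]], tolerance = 1e-12)
  }
})

test_that("bleaching reshapes both channels and gamma is exact at the step", {
  cfg <- sim_config(n_frames_donor_exc = 300, state_means = 0.6,
                    state_occupancies = 1, gamma_range = c(2, 2),
                    leakage_alpha = 0, background_sigma = 0,
                    shot_noise = FALSE, acceptor_bleach_lifetime = 10,
                    donor_bleach_lifetime = 20, seed = 6)
  sim <- simulate_traces(cfg, 20)
  tr_ok <- FALSE
  for (k in 1:20) {
    ta <- sim$truth$acceptor_bleach_frame[k]
    td <- sim$truth$donor_bleach_frame[k]
    if (is.na(ta) || is.na(td) || ta + 5 > td || td > 290 || ta < 10) next
    tr <- sim$traces[[k]]
    # donor recovers by dIa / gamma at acceptor bleach; acceptor drops to 0
    dIa <- tr$acceptor[ta - 1] - tr$acceptor[ta]
    dId <- tr$donor[ta] - tr$donor[ta - 1]
    expect_equal(dIa / dId, 2, tolerance = 1e-12)
    expect_equal(tr$acceptor[ta], 0)
    # after donor bleach both channels at background
    expect_equal(tr$donor[td], 0)
    # direct-excitation segment dark once the acceptor has bleached
    expect_equal(tr$direct, rep(0, cfg$n_frames_acceptor_exc))
    tr_ok <- TRUE
  }
  expect_true(tr_ok)
})

test_that("two-state occupancy matches the analytic stationary distribution", {
  # symmetric 0.5/s rates: closed-form stationary distribution is (1/2, 1/2)
  rates <- matrix(c(0, 0.5, 0.5, 0), 2, 2, byrow = TRUE)
  pi_analytic <- c(0.5, 0.5)
  expect_equal(smfretr:::stationary_distribution(rates), pi_analytic,
               tolerance = 1e-10, ignore_attr = TRUE)
  cfg <- sim_config(n_frames_donor_exc = 500, state_means = c(0.3, 0.8),
                    state_occupancies = pi_analytic,
                    transition_rates = rates, background_sigma = 0,
                    shot_noise = FALSE, donor_bleach_lifetime = 1e9,
                    acceptor_bleach_lifetime = 1e9, seed = 8)
  sim <- simulate_traces(cfg, 20)  # 10 000 molecule-frames
  occ_high <- mean(unlist(sim$state_paths) == 2L)
  # binomial-style sampling band (correlated frames; use a generous 5 sigma
  # of the effective sample: ~ n_frames * (1 - autocorr) independent draws)
  expect_lt(abs(occ_high - 0.5), 0.05)

  # asymmetric rates: pi = (k21, k12) / (k12 + k21)
  rates2 <- matrix(c(0, 1.5, 0.5, 0), 2, 2, byrow = TRUE)
  expect_equal(smfretr:::stationary_distribution(rates2), c(0.25, 0.75),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("simulation is deterministic under a fixed seed and order-free", {
  cfg <- sim_config(n_frames_donor_exc = 100, seed = 99,
                    contaminant_fractions = c(donor_only = 0.1,
                                              acceptor_only = 0.1,
                                              aggregate = 0.1))
  s1 <- simulate_traces(cfg, 20)
  s2 <- simulate_traces(cfg, 20)
  expect_identical(s1$traces, s2$traces)
  expect_identical(s1$truth, s2$truth)
  # class composition is the exact largest-remainder apportionment
  expect_equal(sort(as.vector(table(s1$truth$class))),
               sort(c(good = 14L, donor_only = 2L, acceptor_only = 2L,
                      aggregate = 2L)), ignore_attr = TRUE)
})

test_that("contaminant classes carry the intended signatures", {
  cfg <- sim_config(n_frames_donor_exc = 200, background_sigma = 0,
                    shot_noise = FALSE, leakage_alpha = 0.07,
                    donor_bleach_lifetime = 1e9,
                    acceptor_bleach_lifetime = 1e9, seed = 12,
                    contaminant_fractions = c(donor_only = 1))
  tr <- simulate_traces(cfg, 2)$traces[[1]]
  expect_equal(tr$acceptor, 0.07 * tr$donor)   # leakage only
  expect_equal(tr$direct, rep(0, 10))          # no acceptor to excite

  cfg_a <- sim_config(n_frames_donor_exc = 200, background_sigma = 0,
                      shot_noise = FALSE, donor_bleach_lifetime = 1e9,
                      acceptor_bleach_lifetime = 1e9, seed = 12,
                      contaminant_fractions = c(acceptor_only = 1))
  tra <- simulate_traces(cfg_a, 2)$traces[[1]]
  expect_equal(tra$donor, rep(0, 200))
  expect_equal(tra$acceptor, rep(0, 200))      # no FRET without a donor
  expect_equal(tra$direct, rep(1000, 10))      # but direct excitation works

  cfg_g <- sim_config(n_frames_donor_exc = 200, background_sigma = 0,
                      shot_noise = FALSE, donor_bleach_lifetime = 1e9,
                      acceptor_bleach_lifetime = 1e9, seed = 12,
                      contaminant_fractions = c(aggregate = 1))
  simg <- simulate_traces(cfg_g, 3)
  expect_true(all(simg$truth$n_units >= 2))
})

test_that("particle patterns carry exact ground truth", {
  pp <- simulate_particle_pattern(3, c(2, 4, 6), cluster_sigma = 20,
                                  field = c(5000, 5000), seed = 3)
  expect_equal(sort(pp$truth$sizes), c(2, 4, 6))
  expect_equal(sort(as.integer(table(pp$points$cluster))), c(2, 4, 6))

  empty <- simulate_particle_pattern(0, integer(0), background_density = 0,
                                     seed = 1)
  expect_equal(nrow(empty$points), 0L)

  # shifted-Poisson sizes: analytic mean of Poisson(5) + 1 is 6
  pp2 <- simulate_particle_pattern(100, function(n) rpois(n, 5) + 1,
                                   cluster_sigma = 20,
                                   field = c(60000, 60000),
                                   min_center_separation = 500, seed = 7)
  m <- mean(pp2$truth$sizes)
  se <- sqrt(5 / 100)  # var of shifted Poisson mean
  expect_lt(abs(m - 6), 3 * se)
})
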