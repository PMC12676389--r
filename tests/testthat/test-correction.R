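test_that("leakage subtraction is exact, linear and invertible", {
  expect_equal(subtract_leakage(107, 100, 0.07), 100)
  expect_equal(subtract_leakage(c(50, 80), c(10, 20), 0), c(50, 80))
  expect_error(subtract_leakage(1:3, 1:2, 0.07), "same length")
  # invertible given alpha and the donor series
  set.seed(1)
  don <- runif(50, 0, 1000); acc <- runif(50, 0, 1000)
  corrected <- subtract_leakage(acc, don, 0.07)
  expect_equal(corrected + 0.07 * don, acc, tolerance = 1e-12)
})

test_that("leakage-corrected zero-FRET molecules have zero mean acceptor", {
  cfg <- sim_config(n_frames_donor_exc = 500, state_means = 0,
                    state_occupancies = 1, leakage_alpha = 0.07,
                    donor_bleach_lifetime = 1e9,
                    acceptor_bleach_lifetime = 1e9, seed = 3)
  sim <- simulate_traces(cfg, 10)
  for (tr in sim$traces) {
    acc <- subtract_leakage(tr$acceptor, tr$donor, 0.07)
    se <- sd(acc) / sqrt(length(acc))
    expect_lt(abs(mean(acc)), 3 * se)
  }
})

test_that("step detection matches constructed steps and reports none on noise", {
  set.seed(5)
  expect_equal(detect_bleach_steps(rnorm(300, 1000, 10))$step_count, 0L)

  x1 <- make_step_trace(800, 400, c(1000, 0), sigma = 10)
  d1 <- detect_bleach_steps(x1)
  expect_equal(d1$step_count, 1L)
  expect_lte(abs(d1$step_frames - 400), 1)

  x2 <- make_step_trace(700, c(200, 500), c(1000, 500, 0), sigma = 10)
  d2 <- detect_bleach_steps(x2)
  expect_equal(d2$step_count, 2L)
  expect_lte(max(abs(d2$step_frames - c(200, 500))), 1)
})

test_that("segmentation agrees with the exhaustive least-squares oracle", {
  set.seed(11)
  n_match <- 0; n_loc <- 0; n_tot <- 0
  for (i in 1:60) {
    n <- sample(80:600, 1)
    k <- sample(0:2, 1)
    cps <- sort(sample(seq(15, n - 15, by = 1), k))
    while (k == 2 && diff(cps) < 15) cps <- sort(sample(seq(15, n - 15), k))
    levels <- switch(k + 1, 1000, c(1000, 0), c(1000, 450, 0))
    x <- make_step_trace(n, cps, levels, sigma = 50)  # step >= 9 sigma
    det <- detect_bleach_steps(x)
    if (det$step_count == k) {
      n_match <- n_match + 1
      if (k > 0) {
        oc <- oracle_changepoints(x, k)
        n_tot <- n_tot + k
        n_loc <- n_loc + sum(abs(det$step_frames - oc) <= 1)
      }
    }
  }
  expect_gte(n_match / 60, 0.95)
  expect_equal(n_loc, n_tot)  # within +/- 1 frame of the oracle throughout
})

test_that("gamma estimator reproduces hand-computed values and is exact noise-free", {
  # pre: Id = 100, Ia = 100; post: Id = 200, Ia = 0 -> gamma = 1
  don <- c(rep(100, 100), rep(200, 100))
  acc <- c(rep(100, 100), rep(0, 100))
  g <- estimate_gamma(don, acc, 101L)
  expect_equal(g$gamma, 1)
  # pre: Id = 100, Ia = 300; post: Id = 250 -> gamma = 300 / 150 = 2
  don2 <- c(rep(100, 100), rep(250, 100))
  acc2 <- c(rep(300, 100), rep(0, 100))
  expect_equal(estimate_gamma(don2, acc2, 101L)$gamma, 2)
  # no donor recovery -> undefined with reason
  don3 <- c(rep(100, 100), rep(100, 100))
  g3 <- estimate_gamma(don3, acc2, 101L)
  expect_true(is.na(g3$gamma))
  expect_equal(g3$reason, "gamma_undefined")
  # exactness on a noise-free simulated trace via the full correction path
  tr <- make_good_trace(E = 0.7, gamma = 1.8, ta = 180, td = 340, sigma = 0)
  ct <- correct_trace(tr)
  expect_equal(ct$gamma, 1.8, tolerance = 1e-9)
})

test_that("gamma recovery is accurate across the accepted range at default noise", {
  cfg <- sim_config(seed = 77)
  sim <- simulate_traces(cfg, 120)
  cts <- correct_traces(sim$traces)
  gam <- vapply(cts, function(x) x$gamma, numeric(1))
  ok <- !is.na(gam)
  expect_gt(sum(ok), 40)
  expect_lte(median(abs(gam[ok] - sim$truth$gamma[ok])), 0.1)
})

test_that("snr follows its definition and caps on noise-free traces", {
  don <- rep(300, 200); acc <- rep(700, 200)
  s <- compute_snr(don, acc)
  expect_equal(s$snr, 1e6)  # capped sentinel

  set.seed(9)
  noise <- rnorm(5000, 0, 200)
  total <- 1000 + noise
  s2 <- compute_snr(total, rep(0, 5000))
  expect_equal(s2$snr, mean(total) / sd(total - runmed(total, 5)),
               tolerance = 1e-6)
  expect_lt(abs(s2$snr - 5), 1)

  expect_equal(compute_snr(rep(1, 10), rep(1, 10))$reason, "short")
})

test_that("default-config molecules land in the intended snr band", {
  cfg <- sim_config(seed = 15)
  sim <- simulate_traces(cfg, 100)
  cts <- correct_traces(sim$traces)
  snrs <- vapply(cts, function(x) x$snr, numeric(1))
  med <- median(snrs, na.rm = TRUE)
  expect_gte(med, 6); expect_lte(med, 12)
})

test_that("anticorrelation is -1 for exact anti-linear series and near 0 under independence", {
  set.seed(4)
  don <- 500 + rnorm(300, 0, 50)
  acc <- 1000 - don
  expect_equal(compute_anticorrelation(don, acc), -1, tolerance = 1e-12)
  # null distribution of Pearson r on 499 diffs: |r| < 0.2 w.h.p.
  r <- compute_anticorrelation(rnorm(500, 500, 30), rnorm(500, 500, 30))
  expect_lt(abs(r), 0.2)
})

test_that("dynamic molecules show strong anticorrelation, strongest at high gamma", {
  cfg <- sim_config_dynamic(seed = 19)
  sim <- simulate_traces(cfg, 150)
  cts <- correct_traces(sim$traces)
  rs <- vapply(cts, function(x) x$anticorrelation_r, numeric(1))
  g <- sim$truth$gamma
  ok <- !is.na(rs)
  expect_lte(median(rs[ok]), -0.3)
  # acceptor transition amplitude scales with gamma: the criterion threshold
  # is met by >= 90% of molecules with gamma >= 1
  hi <- ok & g >= 1
  expect_gte(mean(rs[hi] <= -0.3), 0.9)
  expect_gte(mean(rs[ok] < 0), 0.95)
})

test_that("bleach annotation orders acceptor before donor and flags multi-steps", {
  tr <- make_good_trace(E = 0.6, gamma = 1.2, ta = 200, td = 320, sigma = 15,
                        seed = 2)
  ct <- correct_trace(tr)
  expect_equal(ct$acceptor_bleach_frame, 200L, tolerance = 1)
  expect_equal(ct$donor_bleach_frame, 320L, tolerance = 1)
  expect_equal(ct$acceptor_step_count, 1L)
  expect_equal(ct$donor_step_count, 1L)
  expect_false(ct$dynamic)
  expect_true(ct$bleach_anticorrelated)
  expect_true(ct$acceptor_confirmed)

  # two-step acceptor bleach (an aggregate signature)
  n <- 400
  don <- rep(400, n)
  acc <- make_step_trace(n, c(150, 250), c(1200, 600, 0))
  ct2 <- correct_trace(make_raw_trace(don + rnorm(n, 0, 10),
                                      acc + rnorm(n, 0, 10)))
  expect_equal(ct2$acceptor_step_count, 2L)
})

test_that("corrections refuse to run twice", {
  tr <- make_good_trace(seed = 8)
  ct <- correct_trace(tr)
  expect_error(correct_trace(ct), "already corrected")
})
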