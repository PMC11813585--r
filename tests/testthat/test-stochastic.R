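test_that("hybrid simulation is seed-deterministic", {
  host <- host_params(h_ext = 5600)
  sc <- assemble_scenario("single_burdensome_gene_with_punisher", host = host)
  init <- punisher_low_init(sc)
  cfg <- stochastic_config(seed = 7, n_trajectories = 8, horizon = 2)
  r1 <- simulate_hybrid(sc, cfg, init)
  r2 <- simulate_hybrid(sc, cfg, init)
  expect_identical(r1$p_s, r2$p_s)
  expect_identical(r1$final, r2$final)
  cfg2 <- stochastic_config(seed = 8, n_trajectories = 8, horizon = 2)
  r3 <- simulate_hybrid(sc, cfg2, init)
  expect_false(identical(r1$p_s, r3$p_s))
})

test_that("degenerate (all-continuous) partition reproduces the ODE", {
  host <- host_params(h_ext = 5600)
  sc <- assemble_scenario("single_burdensome_gene_with_punisher", host = host)
  init <- punisher_low_init(sc)
  cfg <- stochastic_config(seed = 1, n_trajectories = 2, tau = 0.005,
                           horizon = 5, discrete = character(0))
  hyb <- simulate_hybrid(sc, cfg, init, record = c("p_s", "lambda"))
  ode <- simulate_scenario(sc, horizon = 5, init = init, dt = 0.25)
  lam_ode <- ode$lambda[nrow(ode)]
  lam_hyb <- hyb$lambda[, ncol(hyb$lambda)]
  expect_lt(max(abs(lam_hyb - lam_ode)) / lam_ode, 5e-3)
  ps_ode <- ode$p_s[nrow(ode)]
  expect_lt(max(abs(hyb$p_s[, ncol(hyb$p_s)] - ps_ode)) / ps_ode, 5e-3)
  # degenerate trajectories are identical across the ensemble (no noise)
  expect_equal(hyb$p_s[1, ], hyb$p_s[2, ])
})

test_that("discrete species stay non-negative integer counts", {
  host <- host_params(h_ext = 5600)
  sc <- assemble_scenario("single_burdensome_gene_with_punisher", host = host)
  init <- punisher_low_init(sc)
  cfg <- stochastic_config(seed = 3, n_trajectories = 12, horizon = 3)
  out <- simulate_hybrid(sc, cfg, init, record = c("p_s", "p_i"))
  expect_true(all(out$p_s >= 0))
  expect_true(all(out$p_i >= 0))
  counts <- out$final[, "p_s"] * cfg$vol
  expect_equal(counts, round(counts))
})

test_that("rate_estimate reproduces the exponential MLE and gamma CIs", {
  est <- rate_estimate(10, 25)
  expect_equal(est$rate, 0.4)
  expect_equal(est$ci_low, qgamma(0.025, 10) / 25)
  expect_equal(est$ci_high, qgamma(0.975, 11) / 25)
  expect_false(est$flagged)
  # zero events: rate 0, one-sided upper bound, flagged
  z <- rate_estimate(0, 50)
  expect_equal(z$rate, 0)
  expect_equal(z$ci_low, 0)
  expect_equal(z$ci_high, qgamma(0.95, 1) / 50)
  expect_equal(z$ci_high, -log(0.05) / 50)
  expect_true(z$flagged)
  expect_error(rate_estimate(1, 0), "positive")
})

test_that("telegraph benchmark recovers both rates within 20%", {
  soj <- simulate_telegraph(k_on = 0.4, k_off = 1.3, horizon = 2000, seed = 1)
  est <- estimate_telegraph_rates(soj)
  expect_lt(abs(est$k_on$rate - 0.4) / 0.4, 0.2)
  expect_lt(abs(est$k_off$rate - 1.3) / 1.3, 0.2)
  expect_true(est$k_on$ci_low < 0.4 && 0.4 < est$k_on$ci_high)
  expect_true(est$k_off$ci_low < 1.3 && 1.3 < est$k_off$ci_high)
})

test_that("switch-broken backgrounds have zero activation rate by construction", {
  est <- estimate_transition_rates("s", config = stochastic_config(
    n_trajectories = 2, horizon = 1))
  expect_equal(est$rate, 0)
  expect_equal(est$from, "L")
  expect_equal(est$to, "H")
})
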