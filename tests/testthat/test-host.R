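test_that("competition denominator closed forms: D = 1 and D = 2", {
  hp <- host_params()
  # no mRNA, no drug, no protease load: D = 1
  expect_equal(competition_denominator(0, 0, 0, 1, 1, hp), 1)
  # unit m/k demand: D = 2
  expect_equal(competition_denominator(1, 0, 0, 1, 1, hp), 2)
})

test_that("chloramphenicol inflates D by the prefactor (K_D + h)/K_D", {
  hp <- host_params()
  h <- 2 * hp$K_D
  q <- (hp$K_D + h) / hp$K_D
  expect_equal(competition_denominator(1, h, 0, 1, 1, hp), q * 2)
})

test_that("protease correction reduces D and respects guards", {
  hp <- host_params()
  d0 <- competition_denominator(2, 0, 0, 60000, 40000, hp)
  d1 <- competition_denominator(2, 0, 1e7, 60000, 40000, hp)
  expect_lt(d1, d0)
  expect_error(competition_denominator(2, 0, 1e7, 0, 40000, hp), "positive")
  expect_error(competition_denominator(-1, 0, 0, 1, 1, hp), "non-negative")
})

test_that("rate kernel half-saturations and growth law", {
  hp <- host_params()
  st <- c(t_c = hp$K_eps, t_u = 0, R = 1e4, h = 0)
  rt <- rate_kernel(st, hp, mk_sum = 1, delta = 0)
  expect_equal(rt$eps, hp$eps_max / 2)
  expect_equal(rt$F_r, 1)           # no uncharged tRNA
  expect_equal(rt$B, st[["R"]] * 1 / rt$D)
  expect_equal(rt$lambda, rt$eps * rt$B / ((1 - hp$phi_q) * hp$M))
  st2 <- c(t_c = 1e4, t_u = 1e4, R = 1e4, h = 0)
  rt2 <- rate_kernel(st2, hp, 1, 0)
  expect_equal(rt2$F_r, 0.5)        # tau_ppGpp = 1, equal pools
  expect_equal(rt2$nu, hp$nu_max * hp$sigma * 1e4 / (1e4 + hp$K_nu))
})

test_that("host-only scenario reaches a positive steady state", {
  sc <- assemble_scenario("host_only")
  ss <- steady_state(sc, horizon = 80)
  expect_true(ss$converged)
  expect_gt(ss$rates[["lambda"]], 0.5)
  expect_lt(ss$rates[["lambda"]], 3)
  expect_true(all(ss$state[c("m_a", "m_r", "p_a", "R", "t_c", "t_u")] > 0))
})

test_that("burdensome gene expression lowers the host growth rate", {
  ss0 <- steady_state(assemble_scenario("host_only"), horizon = 80)
  ss1 <- steady_state(assemble_scenario("single_burdensome_gene"),
                      horizon = 80)
  expect_lt(ss1$rates[["lambda"]], ss0$rates[["lambda"]])
})
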