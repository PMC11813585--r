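test_that("switch regulation Hill half-saturation identity", {
  pp <- punisher_params()
  p_half <- pp$K_s / pp$I   # I * p_s = K_s
  expect_equal(switch_regulation(p_half, pp),
               pp$F_sb + (1 - pp$F_sb) / 2)
  expect_equal(switch_regulation(0, pp), pp$F_sb)
  expect_lt(switch_regulation(1e12, pp), 1 + 1e-9)
})

test_that("excision forward rate half-saturates at p_i = K_bI", {
  pp <- punisher_params()
  d_half <- excision_rhs(1, 0, pp$K_bI, pp, 0)
  d_sat <- excision_rhs(1, 0, 1e12, pp, 0)
  expect_equal(-d_half[["c_cat"]], -d_sat[["c_cat"]] / 2, tolerance = 1e-6)
  expect_equal(-d_sat[["c_cat"]], pp$k_sx_f, tolerance = 1e-6)
})

test_that("DNA conservation: d(c_cat + c_LRi)/dt = -(k_conf + lambda) c_LRi", {
  pp <- punisher_params()
  for (case in list(c(8, 1, 5e3, 0.7), c(2, 4, 2e4, 0), c(10, 0, 0, 1.2))) {
    d <- excision_rhs(case[1], case[2], case[3], pp, case[4])
    expect_equal(d[["c_cat"]] + d[["c_LRi"]],
                 -(pp$k_conf + case[4]) * case[2])
  }
})

test_that("toggle regulation: half-repression at p_rep = K_t, pulses relieve", {
  reg <- toggle_genes()$t11$regulation
  f0 <- toggle_regulation(0, reg, 0)
  expect_equal(f0, 1)
  f_half <- toggle_regulation(reg$K_t, reg, 0)
  expect_equal(f_half, reg$F_tb + (1 - reg$F_tb) / 2)
  # a full-strength pulse removes the repressor entirely
  expect_equal(toggle_regulation(1e6, reg, 1), 1)
  expect_gt(toggle_regulation(1e6, reg, 0.5), toggle_regulation(1e6, reg, 0))
})

test_that("co-expressed integrase transcript identity m_i = m_s n_i / n_s", {
  host <- host_params(h_ext = 5600)
  sc <- assemble_scenario("single_burdensome_gene_with_punisher", host = host)
  y <- scenario_init(sc, seed = c(m_s = 120, p_s = 500, p_i = 50,
                                  m_prot = 30, p_prot = 1e4))
  out <- scenario_rhs(0, y, sc)
  gi <- sc$punisher$genes$i
  gs <- sc$punisher$genes$s
  rt <- rate_kernel(y, host, mk_sum_of(sc, y), delta_of(sc, y))
  m_i <- y[["m_s"]] * gi$n_x / gs$n_x
  expected <- rt$eps / gi$n_x * (m_i / gi$k_x) / rt$D * y[["R"]] -
    (gi$delta_x * y[["p_prot"]] + rt$lambda) * y[["p_i"]]
  expect_equal(unname(out[[1]]["p_i"]), expected, tolerance = 1e-10)
})

test_that("chloramphenicol balance has the expected fixed point", {
  # kappa (h_ext - h) = h p_cat / K_C + lambda h
  h_star <- 10 * 5600 / (10 + 80000 / 200 + 1)
  expect_equal(chloramphenicol_rhs(h_star, 80000, 10, 5600, 200, 1), 0,
               tolerance = 1e-9)
  expect_lt(chloramphenicol_rhs(h_star * 2, 80000, 10, 5600, 200, 1), 0)
})
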