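host_t <- host_params(h_ext = 5600)
sc_t <- assemble_scenario("single_burdensome_gene_with_punisher",
                          host = host_t)
bs_t <- burden_summary(sc_t)
pp_t <- punisher_params()

test_that("gene_burden and total_burden basics", {
  expect_equal(gene_burden(0.5, 10, 2, 4), 2.5)
  expect_error(gene_burden(1, 1, 1, 0), "k_bar")
  expect_error(gene_burden(-1, 1, 1, 1), ">= 0")
  xi <- c(a = 1, r = 2, b = 3, s = 100, i = 50)
  expect_equal(total_burden(xi), 6)  # switch and integrase excluded
})

test_that("required regulation: zero at p_s = 0, linear in Xi, capped", {
  expect_equal(required_regulation(0, 10, bs_t, host_t, pp_t), 0)
  expect_equal(required_regulation(0, 1e3, bs_t, host_t, pp_t), 0)
  r1 <- required_regulation(500, 40, bs_t, host_t, pp_t)
  r2 <- required_regulation(500, 80, bs_t, host_t, pp_t)
  expect_equal(r2, 2 * r1)
  expect_gt(r1, 0)
  # above the physical cap: strict errors, lenient returns NA
  cap <- host_t$M * (1 - host_t$phi_q) / pp_t$genes$s$n_x *
    bs_t$xi_s_max / (bs_t$xi_s_max + bs_t$xi_i_max) / (1 + bs_t$chi)
  expect_error(required_regulation(cap * 2, 40, bs_t, host_t, pp_t),
               "unreachable")
  expect_warning(
    out <- required_regulation(cap * 2, 40, bs_t, host_t, pp_t,
                               strict = FALSE), NA)
  expect_true(is.na(out))
})

test_that("fixed points match a dense-grid sign-change oracle", {
  for (Xi in c(20, 80, 300)) {
    fp <- find_fixed_points(Xi, pp_t, bs_t, host_t)
    # oracle: sign changes of F_real - F_req on an independent dense grid
    cap <- host_t$M * (1 - host_t$phi_q) / pp_t$genes$s$n_x *
      bs_t$xi_s_max / (bs_t$xi_s_max + bs_t$xi_i_max) / (1 + bs_t$chi)
    grid <- exp(seq(log(1e-3), log(cap * 0.999), length.out = 20001))
    g <- switch_regulation(grid, pp_t) -
      required_regulation(grid, Xi, bs_t, host_t, pp_t)
    n_oracle <- sum(diff(sign(g)) != 0)
    expect_equal(nrow(fp), n_oracle)
    # every reported fixed point satisfies the defining equation
    resid <- switch_regulation(fp$p_s, pp_t) -
      required_regulation(fp$p_s, Xi, bs_t, host_t, pp_t)
    expect_lt(max(abs(resid)), 1e-6)
    # in the bistable regime fixed points alternate stable/unstable/stable
    if (nrow(fp) == 3) expect_equal(fp$stable, c(TRUE, FALSE, TRUE))
  }
})

test_that("find_threshold separates mono- and bistable burden regimes", {
  Xi_hat <- find_threshold(pp_t, bs_t, host_t)
  expect_false(is.na(Xi_hat))
  p_mid <- pp_t$K_s / pp_t$I
  fp_above <- find_fixed_points(Xi_hat * 1.05, pp_t, bs_t, host_t)
  fp_below <- find_fixed_points(Xi_hat * 0.95, pp_t, bs_t, host_t)
  expect_true(any(fp_above$stable & fp_above$p_s < p_mid))
  expect_false(any(fp_below$stable & fp_below$p_s < p_mid))
})

test_that("integrase activity fold-change bound exceeds 1 when switching", {
  Xi_hat <- find_threshold(pp_t, bs_t, host_t)
  fc <- fold_change_bound(pp_t, bs_t, host_t,
                          Xi_pre = Xi_hat * 1.3, Xi_post = Xi_hat * 0.5)
  expect_true(is.finite(fc))
  expect_gt(fc, 1)
  # no low-expression state to start from when Xi_pre is sub-threshold
  fc2 <- fold_change_bound(pp_t, bs_t, host_t,
                           Xi_pre = Xi_hat * 0.5, Xi_post = Xi_hat * 0.3)
  expect_true(is.na(fc2))
  expect_equal(attr(fc2, "reason"), "no_switching")
})
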