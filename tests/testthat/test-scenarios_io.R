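test_that("minimal config fills documented defaults", {
  cfg <- scenario_config("single_burdensome_gene")
  expect_s3_class(cfg, "scenario_config")
  expect_equal(cfg$schema_version, 1L)
  expect_equal(cfg$kind, "single_cell")
  expect_equal(cfg$conditions$sigma, 0.5)
  expect_equal(cfg$conditions$h_ext, 0)
  expect_equal(cfg$controls$horizon, 50)
  expect_equal(cfg$controls$dt, 0.1)
  expect_equal(cfg$controls$seed, 1)
})

test_that("config validation names the offending symbol", {
  expect_error(scenario_config(kind = "nonsense"), "unknown config kind")
  expect_error(scenario_config("single_burdensome_gene",
                               overrides = list(not_a_param = 3)),
               "not_a_param")
  expect_error(scenario_config("single_burdensome_gene",
                               conditions = list(temperature = 37)),
               "temperature")
  expect_error(scenario_config("single_burdensome_gene",
                               controls = list(warp = 9)), "warp")
  expect_error(scenario_config(kind = "single_cell"), "topology")
  expect_error(scenario_config("no_such_topology"), "topology")
  # a legitimate override is accepted and propagated
  cfg <- scenario_config("single_burdensome_gene",
                         overrides = list(c_b = 50))
  sc <- config_scenario(cfg)
  expect_equal(sc$genes$b$c_x, 50)
})

test_that("YAML dump/load round-trips a config", {
  cfg <- scenario_config("two_toggles_with_punisher",
                         overrides = list(alpha_t = 800),
                         conditions = list(h_ext = 5600),
                         controls = list(horizon = 30, seed = 4))
  path <- tempfile(fileext = ".yaml")
  dump_config(cfg, path)
  cfg2 <- load_config(path)
  expect_equal(unclass(cfg2), unclass(cfg))
  unlink(path)
})

test_that("load_config rejects unknown keys and bad schema versions", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("kind: single_cell", "topology: single_burdensome_gene",
               "surprise: 1"), path)
  expect_error(load_config(path), "surprise")
  writeLines(c("schema_version: 2", "kind: single_cell",
               "topology: single_burdensome_gene"), path)
  expect_error(load_config(path), "schema_version")
  unlink(path)
  expect_error(load_config("/nonexistent/file.yaml"), "not found")
})

test_that("fixtures enumerate, build, and an unknown name errors", {
  for (nm in c("fig1_single_gene", "fig3_two_toggles", "fig3_flip_pulse",
               "fig4_coexpression", "fig5_population",
               "telegraph_benchmark")) {
    fx <- make_fixture(nm)
    expect_s3_class(fx$config, "scenario_config")
    expect_true(length(fx$assertions) >= 1)
  }
  expect_error(make_fixture("fig9_imaginary"), "unknown fixture")
})

test_that("telegraph fixture runs end to end and passes its checks", {
  out <- run_fixture("telegraph_benchmark")
  expect_true(all(out$checks))
})
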