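#' Scenario configuration schema
#'
#' A validated, fully defaulted description of a runnable experiment. Kinds:
#' \describe{
#'  \item{single_cell}{one scenario topology integrated over a horizon}
#'  \item{coexpression_scan}{the CAT RBS-strength scan}
#'  \item{population}{the 48-state turbidostat run (Punisher vs control)}
#'  \item{telegraph}{the telegraph benchmark for the rate estimator}
#' }
#' Parameter overrides must name symbols that exist in the packaged registry
#' (host parameters, top-level Punisher parameters, the burdensome gene's
#' c_b/alpha_b, or the co-expression k_plus_cat/k_off_cat).
#'
#' @param topology topology name (single_cell kind) or NULL
#' @param kind config kind (see above)
#' @param overrides named list of parameter overrides
#' @param events list of mutation events (list(time =, genes =))
#' @param pulses list of inducer pulses
#' @param conditions list: sigma, h_ext, I
#' @param controls list: horizon, dt, seed, and kind-specific controls
#'   (t_cult, mu, n_trajectories, tau, k_range, n_points, k_on, k_off)
#' @return object of class `scenario_config`
#' @export
scenario_config <- function(topology = NULL, kind = "single_cell",
                            overrides = list(), events = list(),
                            pulses = list(), conditions = list(),
                            controls = list()) {
  kinds <- c("single_cell", "coexpression_scan", "population", "telegraph")
  if (!kind %in% kinds) stop("unknown config kind: ", kind)
  cond_def <- list(sigma = 0.5, h_ext = 0, I = punisher_params()$I)
  bad <- setdiff(names(conditions), names(cond_def))
  if (length(bad)) stop("unknown condition field: ", paste(bad, collapse = ", "))
  conditions <- utils::modifyList(cond_def, conditions)
  ctrl_def <- list(horizon = 50, dt = 0.1, seed = 1, t_cult = 500,
                   mu = 1e-12, n_trajectories = 200, tau = 0.01,
                   k_range = c(0.24, 60), n_points = 20, k_off_cat = 2e5,
                   k_on = 0.4, k_off = 1.3)
  bad <- setdiff(names(controls), names(ctrl_def))
  if (length(bad)) stop("unknown control field: ", paste(bad, collapse = ", "))
  controls <- utils::modifyList(ctrl_def, controls)
  validate_overrides(overrides)
  if (kind == "single_cell" && is.null(topology))
    stop("single_cell config requires a topology")
  cfg <- list(schema_version = 1L, kind = kind, topology = topology,
              overrides = overrides, events = events, pulses = pulses,
              conditions = conditions, controls = controls)
  class(cfg) <- c("scenario_config", "list")
  # topology and event validation via scenario assembly
  if (kind == "single_cell") config_scenario(cfg)
  cfg
}

validate_overrides <- function(overrides) {
  if (length(overrides) == 0) return(invisible(TRUE))
  if (is.null(names(overrides)) || any(names(overrides) == ""))
    stop("overrides must be named")
  known <- c(names(host_params()),
             names(Filter(is.numeric, punisher_params())),
             "c_b", "alpha_b", "alpha_t", "k_plus_cat", "k_off_cat", "c_si")
  bad <- setdiff(names(overrides), known)
  if (length(bad))
    stop("unknown parameter symbol in overrides: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Load a scenario configuration from a YAML file
#'
#' Fills defaults from the packaged registry, rejects unknown keys, and
#' validates override symbols, event ordering and topology.
#' @param path YAML file path
#' @return `scenario_config`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- c("schema_version", "kind", "topology", "overrides", "events",
             "pulses", "conditions", "controls")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key: ", paste(bad, collapse = ", "))
  if (!is.null(raw$schema_version) && raw$schema_version != 1)
    stop("unsupported schema_version: ", raw$schema_version)
  scenario_config(topology = raw$topology,
                  kind = if (is.null(raw$kind)) "single_cell" else raw$kind,
                  overrides = if (is.null(raw$overrides)) list() else
                    raw$overrides,
                  events = if (is.null(raw$events)) list() else raw$events,
                  pulses = if (is.null(raw$pulses)) list() else raw$pulses,
                  conditions = if (is.null(raw$conditions)) list() else
                    raw$conditions,
                  controls = if (is.null(raw$controls)) list() else
                    raw$controls)
}

#' Write a scenario configuration to a YAML file
#' @param cfg `scenario_config`
#' @param path output path
#' @export
dump_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# host/punisher parameter objects implied by a config
config_params <- function(cfg) {
  ov <- cfg$overrides
  host <- host_params(sigma = cfg$conditions$sigma,
                      h_ext = cfg$conditions$h_ext)
  for (nm in intersect(names(ov), names(host))) host[[nm]] <- ov[[nm]]
  pp_args <- list(I = cfg$conditions$I)
  if (!is.null(ov$c_si)) pp_args$c_si <- ov$c_si
  pp <- do.call(punisher_params, pp_args)
  for (nm in intersect(names(ov), names(Filter(is.numeric, pp))))
    pp[[nm]] <- ov[[nm]]
  list(host = host, punisher = pp, overrides = ov)
}

#' Build the scenario described by a single-cell config
#' @param cfg `scenario_config` of kind "single_cell"
#' @return a `scenario`
#' @export
config_scenario <- function(cfg) {
  if (cfg$kind != "single_cell")
    stop("config_scenario requires a single_cell config")
  p <- config_params(cfg)
  args <- list(topology = cfg$topology, host = p$host,
               punisher = p$punisher, events = cfg$events,
               pulses = cfg$pulses)
  if (!is.null(p$overrides$k_plus_cat)) {
    args$k_plus_cat <- p$overrides$k_plus_cat
    args$k_off_cat <- if (is.null(p$overrides$k_off_cat))
      cfg$controls$k_off_cat else p$overrides$k_off_cat
  }
  sc <- do.call(assemble_scenario, args)
  if (!is.null(p$overrides$c_b)) sc$genes$b$c_x <- p$overrides$c_b
  if (!is.null(p$overrides$alpha_b)) sc$genes$b$alpha_x <- p$overrides$alpha_b
  if (!is.null(p$overrides$alpha_t))
    for (g in grep("^t[12][12]$", names(sc$genes), value = TRUE))
      sc$genes[[g]]$alpha_x <- p$overrides$alpha_t
  sc
}

#' Packaged experiment fixtures
#'
#' Self-contained configurations reproducing the packaged experiments,
#' bundled with the qualitative assertions their tests exercise.
#' Fixtures: fig1_single_gene, fig3_two_toggles, fig3_flip_pulse,
#' fig4_coexpression, fig5_population, telegraph_benchmark.
#'
#' @param name fixture name
#' @return list(config = `scenario_config`, assertions = character vector)
#' @export
make_fixture <- function(name) {
  fx <- switch(name,
    fig1_single_gene = list(
      config = scenario_config(
        topology = "single_burdensome_gene_with_punisher",
        conditions = list(h_ext = 5600),
        events = list(list(time = 20, genes = "b")),
        controls = list(horizon = 60, dt = 0.1)),
      assertions = c(
        "growth rate rises after the burdensome gene mutates",
        "the switch then activates (p_s crosses the basin threshold)",
        "CAT is excised (dna_cat falls below 5% of its copy number)",
        "final growth rate falls below the pre-mutation rate",
        "the punished growth rate persists to the end of the run")),
    fig3_two_toggles = list(
      config = scenario_config(
        topology = "two_toggles_with_punisher",
        conditions = list(h_ext = 5600),
        controls = list(horizon = 60, dt = 0.1)),
      assertions = c(
        "both toggles hold their seeded branch (ON gene above OFF gene)",
        "the Punisher stays in its low state (no excision)")),
    fig3_flip_pulse = list(
      config = scenario_config(
        topology = "two_toggles_with_punisher",
        conditions = list(h_ext = 5600),
        pulses = list(
          list(start = 5, duration = 2, pulse_id = 2, level = 1),
          list(start = 5, duration = 2, pulse_id = 4, level = 1)),
        controls = list(horizon = 60, dt = 0.1)),
      assertions = c(
        "both toggles flip to the opposite branch after the pulse",
        "CAT DNA stays within 1% of its initial copy number",
        "the switch stays in its low basin throughout")),
    fig4_coexpression = list(
      config = scenario_config(
        kind = "coexpression_scan",
        conditions = list(h_ext = 5600),
        controls = list(k_range = c(0.24, 60), n_points = 20,
                        k_off_cat = 2e5, horizon = 50)),
      assertions = c(
        "the scan covers the printed RBS range 0.24 to 60 nM^-1 h^-1",
        "relative mutant growth is reported for every mutant class",
        "an acceptable sub-range (no mutant out-grows unmutated) is located")),
    fig5_population = list(
      config = scenario_config(
        kind = "population",
        conditions = list(h_ext = 5600),
        controls = list(t_cult = 500, mu = 1e-12, n_trajectories = 200,
                        tau = 0.01, horizon = 20, seed = 1)),
      assertions = c(
        "total cell count is conserved by the turbidostat",
        "the Punisher population keeps productivity above half-maximum longer than the control",
        "the control's mutant fraction rises monotonically")),
    telegraph_benchmark = list(
      config = scenario_config(
        kind = "telegraph",
        controls = list(k_on = 0.4, k_off = 1.3, horizon = 2000, seed = 1)),
      assertions = c(
        "both telegraph rates are recovered within 20% with >= 500 events")),
    stop("unknown fixture: ", name))
  fx$name <- name
  fx
}

#' Run a packaged fixture end-to-end
#'
#' Executes the fixture's experiment and evaluates its assertion bundle.
#' @param name fixture name (see [make_fixture])
#' @param seed RNG seed for stochastic fixtures (defaults to the fixture's)
#' @return list(name, result, checks = named logical vector, config)
#' @export
run_fixture <- function(name, seed = NULL) {
  fx <- make_fixture(name)
  cfg <- fx$config
  if (!is.null(seed)) cfg$controls$seed <- seed
  p <- config_params(cfg)
  checks <- c()
  result <- NULL

  if (name == "fig1_single_gene") {
    sc <- config_scenario(cfg)
    init <- punisher_low_init(sc)
    traj <- simulate_scenario(sc, horizon = cfg$controls$horizon,
                              init = init, dt = cfg$controls$dt)
    thr <- background_threshold(character(0), p$host, p$punisher)
    t_mut <- cfg$events[[1]]$time
    pre <- traj$lambda[max(which(traj$time <= t_mut))]
    post_peak <- max(traj$lambda[traj$time > t_mut])
    fin <- traj$lambda[nrow(traj)]
    checks <- c(
      growth_rises_after_mutation = post_peak > pre * 1.05,
      switch_activates = max(traj$p_s) > thr,
      cat_excised = traj$dna_cat[nrow(traj)] <
        0.05 * p$punisher$genes$cat$c_x,
      growth_collapses = fin < pre,
      punishment_persists = all(
        traj$lambda[traj$time > traj$time[which.min(traj$lambda)]] <= pre))
    result <- traj
  } else if (name %in% c("fig3_two_toggles", "fig3_flip_pulse")) {
    sc <- config_scenario(cfg)
    init <- punisher_low_init(sc, seed = c(p_t11 = 3e5, p_t21 = 3e5))
    traj <- simulate_scenario(sc, horizon = cfg$controls$horizon,
                              init = init, dt = cfg$controls$dt)
    n <- nrow(traj)
    flipped <- traj$p_t12[n] > traj$p_t11[n] && traj$p_t22[n] > traj$p_t21[n]
    held <- traj$p_t11[n] > traj$p_t12[n] && traj$p_t21[n] > traj$p_t22[n]
    dna_ok <- abs(traj$dna_cat[n] - traj$dna_cat[1]) <=
      0.01 * traj$dna_cat[1]
    thr <- p$punisher$K_s / p$punisher$I
    low <- max(traj$p_s) < thr
    checks <- if (name == "fig3_two_toggles")
      c(branches_held = held, punisher_low = low && dna_ok) else
      c(toggles_flipped = flipped, cat_dna_within_1pct = dna_ok,
        punisher_low = low)
    result <- traj
  } else if (name == "fig4_coexpression") {
    kr <- cfg$controls$k_range
    grid <- exp(seq(log(kr[1]), log(kr[2]),
                    length.out = cfg$controls$n_points))
    scan <- coexpression_scan(grid, host = p$host,
                              k_off_cat = cfg$controls$k_off_cat,
                              horizon = cfg$controls$horizon)
    checks <- c(
      covers_printed_range = abs(min(grid) - 0.24) < 1e-9 &&
        abs(max(grid) - 60) < 1e-9,
      all_classes_reported = all(names(coexpression_mutant_classes()) %in%
                                   names(scan$table)),
      window_located = any(scan$table$acceptable))
    result <- scan
  } else if (name == "fig5_population") {
    ctrl <- cfg$controls
    scfg <- stochastic_config(seed = ctrl$seed,
                              n_trajectories = ctrl$n_trajectories,
                              tau = ctrl$tau, horizon = ctrl$horizon)
    model <- population_model(host = p$host, punisher = p$punisher,
                              mu = ctrl$mu, t_cult = ctrl$t_cult,
                              config = scfg)
    trajP <- simulate_population(model, population_init(model, "punisher"))
    trajC <- simulate_population(model, population_init(model, "control"))
    pm <- productivity_metrics(trajP, model)
    cm <- productivity_metrics(trajC, model)
    tot <- rowSums(trajP[, model$states])
    ctrl_lbl <- state_label(TRUE, FALSE, FALSE, TRUE, "0")
    mut_frac <- 1 - trajC[[ctrl_lbl]] / rowSums(trajC[, model$states])
    checks <- c(
      total_conserved = max(abs(tot - tot[1])) < 1e-6 * tot[1],
      punisher_outlasts_control = pm$tau > cm$tau,
      control_mutants_monotone = all(diff(mut_frac) > -1e-9))
    result <- list(model = model, punisher = pm, control = cm,
                   tau_ratio = pm$tau / cm$tau)
  } else if (name == "telegraph_benchmark") {
    ctrl <- cfg$controls
    soj <- simulate_telegraph(ctrl$k_on, ctrl$k_off, ctrl$horizon,
                              seed = ctrl$seed)
    est <- estimate_telegraph_rates(soj)
    checks <- c(
      enough_events = nrow(soj) >= 500,
      k_on_within_20pct = abs(est$k_on$rate - ctrl$k_on) <= 0.2 * ctrl$k_on,
      k_off_within_20pct = abs(est$k_off$rate - ctrl$k_off) <=
        0.2 * ctrl$k_off)
    result <- list(sojourns = soj, estimates = est)
  }

  list(name = name, result = result, checks = checks, config = cfg)
}
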