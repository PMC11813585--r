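#' Assemble a named circuit topology into a simulatable scenario
#'
#' Composes the host model with a synthetic circuit into a full ODE system.
#' Available topologies:
#' \describe{
#'  \item{host_only}{no synthetic genes}
#'  \item{single_burdensome_gene}{one constitutive burdensome gene, no
#'    mutation penalisation}
#'  \item{burdensome_gene_no_punisher}{burdensome gene plus constitutively
#'    expressed CAT (chloramphenicol resistance), no Punisher}
#'  \item{single_burdensome_gene_with_punisher}{burdensome gene plus the full
#'    Punisher (switch/integrase/protease/excisable CAT)}
#'  \item{two_toggles}{two mutually repressing toggle switches}
#'  \item{two_toggles_with_punisher}{the toggles plus the full Punisher}
#'  \item{two_toggles_cat_coexpression}{the toggles with a CAT cistron
#'    co-transcribed on every toggle transcript (no Punisher); requires
#'    `k_plus_cat`, the CAT mRNA-ribosome association rate (nM^-1 h^-1)}
#' }
#'
#' @param topology topology name
#' @param host `host_params`
#' @param punisher `punisher_params` (used only by *_with_punisher topologies)
#' @param mutated character vector of gene names whose transcription is lost
#'   from t = 0 ("b", "s" (covers the co-expressed integrase), "prot", "cat",
#'   "t11", ...)
#' @param events list of mutation events, each `list(time =, genes =)`;
#'   mutation zeroes the genes' DNA concentration while existing mRNA and
#'   protein decay naturally
#' @param pulses list of inducer pulses, each
#'   `list(start =, duration =, pulse_id =, level =)` with level in \[0,1\]
#' @param k_plus_cat CAT mRNA-ribosome association rate for the co-expression
#'   topology (nM^-1 h^-1)
#' @param k_off_cat ribosome unbinding rate used to convert the association
#'   rate into a dissociation constant k = (k_off + eps/n_cat)/k_plus (1/h)
#' @param freeze_switch hold the switch regulation at its baseline F_sb
#'   (disables self-activation); used to probe the burden of a genetic
#'   background with the Punisher pinned to its low-expression state
#' @param freeze_excision hold the CAT DNA states fixed (no strand exchange);
#'   used by the population module, where excision is a state transition of
#'   the population model rather than part of a state's internal dynamics
#' @return object of class `scenario`
#' @export
assemble_scenario <- function(topology,
                              host = host_params(),
                              punisher = punisher_params(),
                              mutated = character(),
                              events = list(),
                              pulses = list(),
                              k_plus_cat = NULL,
                              k_off_cat = 60,
                              freeze_switch = FALSE,
                              freeze_excision = FALSE) {
  topologies <- c("host_only", "single_burdensome_gene",
                  "burdensome_gene_no_punisher",
                  "single_burdensome_gene_with_punisher",
                  "two_toggles", "two_toggles_with_punisher",
                  "two_toggles_cat_coexpression")
  if (!topology %in% topologies)
    stop("unknown topology: ", topology)

  genes <- list()
  has_punisher <- grepl("with_punisher", topology)
  coexpression <- NULL

  if (grepl("burdensome_gene", topology)) genes$b <- burdensome_gene()
  if (grepl("toggles", topology)) genes <- c(genes, toggle_genes())
  if (topology == "burdensome_gene_no_punisher")
    genes$cat <- punisher$genes$cat
  if (topology == "two_toggles_cat_coexpression") {
    if (is.null(k_plus_cat))
      stop("two_toggles_cat_coexpression requires k_plus_cat")
    coexpression <- list(k_plus = k_plus_cat, k_off = k_off_cat,
                         n_cat = punisher$genes$cat$n_x)
  }

  sc <- list(topology = topology, host = host,
             punisher = if (has_punisher) punisher else NULL,
             genes = genes, coexpression = coexpression,
             K_C = punisher$K_C, freeze_switch = freeze_switch,
             freeze_excision = freeze_excision,
             mutated = unique(mutated), events = events, pulses = pulses)
  class(sc) <- c("scenario", "list")
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc) {
  known <- scenario_gene_names(sc)
  for (g in sc$mutated)
    if (!g %in% known) stop("unknown mutated gene: ", g)
  if (length(sc$events)) {
    t_ev <- vapply(sc$events, function(e) e$time, numeric(1))
    if (is.unsorted(t_ev)) stop("events must be time-ordered")
    for (e in sc$events)
      for (g in e$genes)
        if (!g %in% known) stop("unknown gene in event: ", g)
  }
  invisible(sc)
}

scenario_gene_names <- function(sc) {
  nm <- names(sc$genes)
  if (!is.null(sc$punisher)) nm <- c(nm, "s", "prot", "cat")
  nm
}

#' Default initial state of a scenario
#'
#' Host states from [host_init], synthetic mRNAs/proteins at zero, CAT DNA at
#' its unexcised copy number and intracellular chloramphenicol at zero. For
#' bistable circuits, seed protein levels can be supplied via `seed`.
#'
#' @param sc a `scenario`
#' @param seed named numeric vector of state overrides
#' @return named numeric state vector
#' @export
scenario_init <- function(sc, seed = c()) {
  y <- host_init(sc$host)
  for (g in names(sc$genes)) {
    y[paste0("m_", g)] <- 0
    y[paste0("p_", g)] <- 0
  }
  if (!is.null(sc$punisher)) {
    y[c("m_s", "p_s", "p_i", "m_prot", "p_prot", "m_cat", "p_cat")] <- 0
    y["dna_cat"] <- if ("cat" %in% sc$mutated) 0 else sc$punisher$genes$cat$c_x
    y["dna_LRi"] <- 0
  }
  if (!is.null(sc$coexpression)) y["p_cat"] <- 0
  if (length(seed)) {
    bad <- setdiff(names(seed), names(y))
    if (length(bad)) stop("unknown state in seed: ", paste(bad, collapse = ", "))
    y[names(seed)] <- seed
  }
  y
}

# effective DNA concentration of a gene given mutation status
effective_c <- function(gene, mutated) {
  if (gene$name %in% mutated) 0 else gene$c_x
}

# inducer occupancy per pulse_id at time t
pulse_levels <- function(pulses, t, n_ids = 4) {
  u <- numeric(n_ids)
  for (p in pulses) {
    if (t >= p$start && t < p$start + p$duration)
      u[p$pulse_id] <- min(1, u[p$pulse_id] + p$level)
  }
  u
}

#' Equilibrate a Punisher scenario in its low-expression state
#'
#' Settles the system with the switch regulation frozen at its baseline
#' (no self-activation, hence no spurious excision during the start-up
#' transient while burden builds from zero), then returns the converged state
#' for use as the initial condition of live simulations. This mirrors growing
#' the engineered strain to equilibrium before the experiment starts.
#'
#' @param sc a `scenario` with the Punisher
#' @param seed named state overrides (e.g. toggle proteins selecting a branch)
#' @param horizon settle horizon (h)
#' @return named state vector at the frozen-switch steady state
#' @export
punisher_low_init <- function(sc, seed = c(), horizon = 100) {
  if (is.null(sc$punisher)) stop("scenario has no Punisher")
  scf <- sc
  scf$freeze_switch <- TRUE
  scf$events <- list()
  ss <- steady_state(scf, init = scenario_init(scf, seed), horizon = horizon)
  ss$state
}

#' Full ODE right-hand side of a scenario
#'
#' Signature compatible with [deSolve::ode]: returns the derivative list plus
#' auxiliary outputs (lambda, eps, D, F_s when the Punisher is present).
#' @param t time (h)
#' @param y named state vector
#' @param sc a `scenario`
#' @param mutated currently mutated gene set (defaults to `sc$mutated`)
#' @return list(derivatives, auxiliaries)
#' @export
scenario_rhs <- function(t, y, sc, mutated = sc$mutated) {
  yp <- pmax(y, 0)   # rate evaluation guards against solver under-shoot
  hp <- sc$host
  pun <- sc$punisher
  u <- pulse_levels(sc$pulses, t)

  # --- collect translational demand (m/k) and protease load -----------------
  mk <- host_mk_sum(yp, hp)
  p_prot <- if (!is.null(pun)) yp[["p_prot"]] else 0
  delta <- 0
  for (g in names(sc$genes)) mk <- mk + yp[[paste0("m_", g)]] / sc$genes[[g]]$k_x
  cx <- NULL
  if (!is.null(sc$coexpression)) {
    eps_now <- hp$eps_max * yp[["t_c"]] / (yp[["t_c"]] + hp$K_eps)
    k_cat_co <- (sc$coexpression$k_off + eps_now / sc$coexpression$n_cat) /
      sc$coexpression$k_plus
    mk_co <- 0
    for (g in names(sc$genes)) mk_co <- mk_co + yp[[paste0("m_", g)]] / k_cat_co
    mk <- mk + mk_co
    cx <- list(k = k_cat_co, mk = mk_co)
  }
  if (!is.null(pun)) {
    gs <- pun$genes$s; gi <- pun$genes$i
    m_s <- yp[["m_s"]]
    m_i <- m_s * gi$n_x / gs$n_x   # co-expression transcript identity
    mk <- mk + m_s / gs$k_x + m_i / gi$k_x +
      yp[["m_prot"]] / pun$genes$prot$k_x + yp[["m_cat"]] / pun$genes$cat$k_x
    delta <- protease_aggregate(
      p_prot,
      n_x = c(gs$n_x, gi$n_x),
      delta_x = c(gs$delta_x, gi$delta_x),
      p_x = c(yp[["p_s"]], yp[["p_i"]]))
  }

  rates <- rate_kernel(yp, hp, mk, delta)
  lam <- rates$lambda

  dy <- host_rhs(yp[c("m_a", "m_r", "p_a", "R", "t_c", "t_u")], hp, rates)

  # --- regular synthetic genes ---------------------------------------------
  aux <- c(lambda = lam, eps = rates$eps, D = rates$D, F_r = rates$F_r,
           B = rates$B)
  p_cat_total <- 0
  for (g in names(sc$genes)) {
    gene <- sc$genes[[g]]
    reg <- gene$regulation
    F_x <- switch(reg$type,
      constitutive = 1,
      toggle_repression = toggle_regulation(
        yp[[paste0("p_", reg$partner)]], reg, u[reg$pulse_id]),
      stop("unsupported regulation type: ", reg$type))
    d <- synthetic_gene_rhs(gene, yp[[paste0("m_", g)]], yp[[paste0("p_", g)]],
                            F_x, rates, yp[["R"]], p_prot,
                            c_x = effective_c(gene, mutated))
    dy[paste0("m_", g)] <- d[["m"]]
    dy[paste0("p_", g)] <- d[["p"]]
    if (g == "cat") p_cat_total <- p_cat_total + yp[["p_cat"]]
  }

  # --- co-expressed CAT cistrons -------------------------------------------
  if (!is.null(sc$coexpression)) {
    synth <- rates$eps / sc$coexpression$n_cat * cx$mk / rates$D * yp[["R"]]
    dy["p_cat"] <- synth - lam * yp[["p_cat"]]
    p_cat_total <- yp[["p_cat"]]
  }

  # --- Punisher block -------------------------------------------------------
  if (!is.null(pun)) {
    gs <- pun$genes$s; gi <- pun$genes$i
    gp <- pun$genes$prot; gc <- pun$genes$cat
    F_s <- if (isTRUE(sc$freeze_switch)) pun$F_sb else
      switch_regulation(yp[["p_s"]], pun)
    ds <- synthetic_gene_rhs(gs, yp[["m_s"]], yp[["p_s"]], F_s, rates,
                             yp[["R"]], p_prot,
                             c_x = effective_c(gs, if ("s" %in% mutated) "s" else character()))
    m_i <- yp[["m_s"]] * gi$n_x / gs$n_x
    dp_i <- rates$eps / gi$n_x * (m_i / gi$k_x) / rates$D * yp[["R"]] -
      (gi$delta_x * p_prot + lam) * yp[["p_i"]]
    dprot <- synthetic_gene_rhs(gp, yp[["m_prot"]], yp[["p_prot"]], 1, rates,
                                yp[["R"]], p_prot,
                                c_x = effective_c(gp, if ("prot" %in% mutated) "prot" else character()))
    dcat <- synthetic_gene_rhs(gc, yp[["m_cat"]], yp[["p_cat"]], 1, rates,
                               yp[["R"]], p_prot, c_x = yp[["dna_cat"]])
    ddna <- if (isTRUE(sc$freeze_excision)) c(c_cat = 0, c_LRi = 0) else
      excision_rhs(yp[["dna_cat"]], yp[["dna_LRi"]], yp[["p_i"]], pun, lam)
    dy["m_s"] <- ds[["m"]]; dy["p_s"] <- ds[["p"]]; dy["p_i"] <- dp_i
    dy["m_prot"] <- dprot[["m"]]; dy["p_prot"] <- dprot[["p"]]
    dy["m_cat"] <- dcat[["m"]]; dy["p_cat"] <- dcat[["p"]]
    dy["dna_cat"] <- ddna[["c_cat"]]; dy["dna_LRi"] <- ddna[["c_LRi"]]
    p_cat_total <- yp[["p_cat"]]
    aux["F_s"] <- F_s
  }

  # --- chloramphenicol ------------------------------------------------------
  dy["h"] <- chloramphenicol_rhs(yp[["h"]], p_cat_total, hp$kappa, hp$h_ext,
                                 sc$K_C, lam)

  list(dy[names(y)], aux)
}

#' Simulate a scenario
#'
#' Integrates the composed ODE system with a stiff solver (lsoda, rtol 1e-8,
#' scaled atol), applying mutation events at their specified times.
#'
#' @param sc a `scenario`
#' @param horizon simulation end time (h)
#' @param init initial state (defaults to [scenario_init])
#' @param dt output time step (h)
#' @param times explicit output times (overrides horizon/dt)
#' @return data.frame: time, all state variables, lambda, eps, D (and F_s for
#'   Punisher topologies); solver under-shoots are clipped to 0 for reporting
#' @export
simulate_scenario <- function(sc, horizon = 50, init = scenario_init(sc),
                              dt = 0.1, times = NULL) {
  if (is.null(times)) times <- seq(0, horizon, by = dt)
  ev_times <- if (length(sc$events))
    vapply(sc$events, function(e) e$time, numeric(1)) else numeric()
  bounds <- sort(unique(c(times[1], ev_times, times[length(times)])))
  mutated <- sc$mutated
  y <- init
  out <- NULL
  for (i in seq_len(length(bounds) - 1)) {
    t0 <- bounds[i]; t1 <- bounds[i + 1]
    for (e in sc$events) if (e$time == t0) mutated <- unique(c(mutated, e$genes))
    seg_times <- unique(c(t0, times[times > t0 & times < t1], t1))
    seg <- deSolve::ode(
      y = y, times = seg_times,
      func = function(t, y, parms) scenario_rhs(t, y, sc, mutated),
      parms = NULL, method = "lsoda",
      rtol = 1e-8, atol = 1e-8 * pmax(abs(y), 1), maxsteps = 500000)
    y <- seg[nrow(seg), names(y)]
    keep <- if (i < length(bounds) - 1) -nrow(seg) else TRUE
    out <- rbind(out, seg[keep, , drop = FALSE])
  }
  out <- as.data.frame(out)
  state_cols <- names(init)
  out[state_cols] <- lapply(out[state_cols], pmax, 0)
  out
}

#' Integrate a scenario to steady state
#'
#' Runs the system until the max norm of scaled derivatives falls below `tol`
#' or the horizon (default 50 h) is reached.
#'
#' @inheritParams simulate_scenario
#' @param tol convergence tolerance on max(|dy| / max(|y|, floor))
#' @param mutated currently mutated gene set
#' @return list(state, rates, converged, time)
#' @export
steady_state <- function(sc, init = scenario_init(sc), horizon = 50,
                         tol = 1e-6, mutated = sc$mutated) {
  stopifnot(length(sc$events) == 0 || horizon <= min(
    vapply(sc$events, function(e) e$time, numeric(1))))
  y <- init
  t_now <- 0
  chunk <- 10
  converged <- FALSE
  stalls <- 0
  while (t_now < horizon) {
    t_end <- min(t_now + chunk, horizon)
    # lsoda may return early when a chunk exhausts its internal step budget;
    # resume from the time actually reached instead of skipping ahead
    seg <- withCallingHandlers(
      deSolve::ode(
        y = y, times = c(t_now, t_end),
        func = function(t, y, parms) scenario_rhs(t, y, sc, mutated),
        parms = NULL, method = "lsoda",
        rtol = 1e-8, atol = 1e-8 * pmax(abs(y), 1), maxsteps = 500000),
      warning = function(w) {
        if (grepl("maxsteps|Returning early|Excess work", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    y <- pmax(seg[nrow(seg), names(y)], 0)
    t_reached <- seg[nrow(seg), "time"]
    if (t_reached < t_end - 1e-9) {
      stalls <- stalls + 1
      if (t_reached <= t_now + 1e-9 || stalls > 50)
        stop("steady_state: integrator stalled at t = ", signif(t_reached, 6))
      t_now <- t_reached
      next
    }
    t_now <- t_end
    dy <- scenario_rhs(t_now, y, sc, mutated)[[1]]
    if (max(abs(dy) / pmax(abs(y), 1e-3)) < tol) {
      converged <- TRUE
      break
    }
  }
  rhs <- scenario_rhs(t_now, y, sc, mutated)
  list(state = y, rates = rhs[[2]], converged = converged, time = t_now)
}
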