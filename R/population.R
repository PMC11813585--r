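#' Canonical enumeration of the 48 population states
#'
#' Each cell is classified by which of the four mutable synthetic units are
#' still functional — B (burdensome gene), S (switch + co-expressed
#' integrase, one unit), P (protease), C (CAT, i.e. unexcised/unmutated
#' resistance DNA) — and by its Punisher expression state ("0" no
#' switch/integrase protein, "L" low, "H" high). Canonical order: genetic
#' states ascending in the binary number B*8 + S*4 + P*2 + C*1 (so index 0 is
#' the fully mutated cell and 15 is BSPC), each expanded over Punisher states
#' in order (0, L, H); linear index = genetic_index * 3 + punisher_index,
#' running 0..47.
#'
#' @return data.frame with columns index (0..47), B, S, P, C (logical:
#'   functional?), punisher ("0"/"L"/"H"), label (e.g. "B\u2032SPC:H")
#' @export
enumerate_states <- function() {
  qs <- c("0", "L", "H")
  rows <- vector("list", 48)
  k <- 0
  for (gi in 0:15) {
    B <- bitwAnd(gi, 8L) > 0; S <- bitwAnd(gi, 4L) > 0
    P <- bitwAnd(gi, 2L) > 0; C <- bitwAnd(gi, 1L) > 0
    for (qi in 0:2) {
      k <- k + 1
      rows[[k]] <- data.frame(
        index = gi * 3 + qi, B = B, S = S, P = P, C = C,
        punisher = qs[qi + 1],
        label = state_label(B, S, P, C, qs[qi + 1]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Render a population-state label
#'
#' Functional units render as their plain letter, mutated units carry a prime
#' (U+2032), followed by ":" and the Punisher state, e.g. "B\u2032SPC:H".
#' @param B,S,P,C logical: unit functional?
#' @param punisher "0", "L" or "H"
#' @export
state_label <- function(B, S, P, C, punisher) {
  pr <- "\u2032"
  paste0("B", if (!B) pr else "", "S", if (!S) pr else "",
         "P", if (!P) pr else "", "C", if (!C) pr else "",
         ":", punisher)
}

#' Parse a population-state label back to its components
#' @param label label string as produced by [state_label] (an ASCII
#'   apostrophe is accepted in place of the prime)
#' @return list(B, S, P, C, punisher, index)
#' @export
parse_state_label <- function(label) {
  parts <- strsplit(label, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !parts[2] %in% c("0", "L", "H"))
    stop("malformed state label: ", label)
  g <- gsub("'", "\u2032", parts[1])
  flags <- logical(4); names(flags) <- c("B", "S", "P", "C")
  pos <- 1
  for (u in names(flags)) {
    if (substr(g, pos, pos) != u) stop("malformed state label: ", label)
    pos <- pos + 1
    if (substr(g, pos, pos) == "\u2032") {
      flags[u] <- FALSE; pos <- pos + 1
    } else flags[u] <- TRUE
  }
  if (pos != nchar(g) + 1) stop("malformed state label: ", label)
  qi <- match(parts[2], c("0", "L", "H")) - 1
  gi <- sum(c(8, 4, 2, 1)[flags])
  list(B = flags[["B"]], S = flags[["S"]], P = flags[["P"]], C = flags[["C"]],
       punisher = parts[2], index = gi * 3 + qi)
}

# mutated-gene set of a genetic state (S covers switch + integrase)
genetic_mutated <- function(B, S, P, C) {
  c(if (!B) "b", if (!S) "s", if (!P) "prot", if (!C) "cat")
}

# package-level cache for the single-cell property library
.pop_cache <- new.env(parent = emptyenv())

#' Single-cell property library for the 48 population states
#'
#' For every state, integrates the single-cell model (with CAT strand
#' exchange frozen: excision is a population-level transition, not part of a
#' state's internal dynamics) to steady state and records the division rate,
#' burdensome-protein content, integrase level and the protease-mediated
#' decay rate of the Punisher proteins. States are initialised according to
#' their Punisher coordinate ("0": no switch/integrase expression; "L": the
#' frozen-switch low steady state; "H": switch/integrase seeded above the
#' saddle). A state whose intended equilibrium does not exist (the settle
#' leaves the intended basin) inherits its closest unmutated progenitor's
#' properties, restoring units in the order B, S, P, C until an existing
#' state is reached.
#'
#' The library is cached per parameter set (keyed by the serialised
#' parameters), so repeated model builds never re-integrate the ODEs.
#'
#' @param host `host_params` (chloramphenicol-containing medium by default)
#' @param punisher `punisher_params`
#' @param cache reuse a previously computed library for identical parameters
#' @return data.frame keyed by label: exists, mapped_from, lambda (1/h),
#'   p_b (nM), p_i (nM), decay_rate (1/h), p_s (nM)
#' @export
single_cell_library <- function(host = host_params(h_ext = 5600),
                                punisher = punisher_params(),
                                cache = TRUE) {
  key <- paste(c(deparse(host), deparse(punisher)), collapse = "\n")
  if (cache && !is.null(.pop_cache[[key]])) return(.pop_cache[[key]])

  st <- enumerate_states()
  thr_cache <- new.env(parent = emptyenv())

  settle_one <- function(B, S, P, C, q) {
    mut <- genetic_mutated(B, S, P, C)
    if (q == "0") mut <- unique(c(mut, "s"))
    sc <- assemble_scenario("single_burdensome_gene_with_punisher",
                            host = host, punisher = punisher,
                            mutated = mut, freeze_excision = TRUE)
    init <- punisher_low_init(sc)
    thr <- NA_real_
    if (S && q != "0") {
      key <- paste0("bg:", paste(mut, collapse = "+"))
      if (is.null(thr_cache[[key]]))
        thr_cache[[key]] <- background_threshold(mut, host, punisher,
                                                 init_low = init)
      thr <- thr_cache[[key]]
    }
    if (q == "H") {
      hi <- max(init[["p_s"]] * 20, if (is.na(thr)) 0 else thr * 10)
      init["p_s"] <- hi
      init["p_i"] <- hi / 4
    }
    ss <- steady_state(sc, init = init, horizon = 60)
    y <- ss$state
    exists <- switch(q,
      "0" = TRUE,
      "L" = if (is.na(thr)) FALSE else
        y[["p_s"]] > 1 && y[["p_s"]] < thr,
      "H" = if (is.na(thr)) FALSE else y[["p_s"]] > thr)
    gp <- punisher$genes
    list(exists = exists,
         lambda = ss$rates[["lambda"]],
         p_b = if (B) y[["p_b"]] else 0,
         p_i = y[["p_i"]], p_s = y[["p_s"]],
         decay_rate = gp$s$delta_x * y[["p_prot"]] + ss$rates[["lambda"]])
  }

  raw <- vector("list", 48)
  for (r in seq_len(48))
    raw[[r]] <- settle_one(st$B[r], st$S[r], st$P[r], st$C[r], st$punisher[r])

  # progenitor mapping: restore units in order B, S, P, C until the
  # equilibrium exists; BSPC:{0,L} and all q="0" states exist by construction
  resolve <- function(r) {
    if (raw[[r]]$exists) return(r)
    for (u in c("B", "S", "P", "C")) {
      if (!st[[u]][r]) {
        g <- st[r, c("B", "S", "P", "C")]
        g[[u]] <- TRUE
        lbl <- state_label(g$B, g$S, g$P, g$C, st$punisher[r])
        return(resolve(which(st$label == lbl)))
      }
    }
    # fully functional but intended equilibrium absent (can only be q = "H"
    # if the high state did not persist): fall back to the low state
    which(st$label == state_label(TRUE, TRUE, TRUE, TRUE, "L"))
  }

  lib <- st
  lib$exists <- vapply(raw, function(x) x$exists, logical(1))
  src <- vapply(seq_len(48), resolve, integer(1))
  lib$mapped_from <- ifelse(src == seq_len(48), NA_character_, st$label[src])
  for (f in c("lambda", "p_b", "p_i", "p_s", "decay_rate"))
    lib[[f]] <- vapply(src, function(r) raw[[r]][[f]], numeric(1))
  # inherited dynamics never restore product synthesis in a b-mutated cell
  lib$p_b[!lib$B] <- 0
  if (cache) .pop_cache[[key]] <- lib
  lib
}

# saddle (unstable fixed point of p_s) of the unmutated background, used to
# classify low vs high Punisher expression
population_saddle <- function(host, punisher) {
  sc <- assemble_scenario("single_burdensome_gene_with_punisher",
                          host = host, punisher = punisher)
  bs <- burden_summary(sc, steady_state(sc))
  fp <- find_fixed_points(bs$Xi, punisher, bs, host)
  saddle <- fp$p_s[!fp$stable]
  if (length(saddle) == 0) punisher$K_s / punisher$I else max(saddle)
}

#' Switch-protein threshold separating low and high Punisher expression
#'
#' For a given genetic background, the basin boundary used for state
#' classification and first-passage detection: the background's unstable
#' fixed point when the switch is bistable there, otherwise (low branch
#' absent, deterministic activation) the geometric mean of the frozen-switch
#' low level and the high fixed point.
#'
#' @param mutated mutated gene set of the background (among "b", "s",
#'   "prot", "cat")
#' @param host,punisher parameters
#' @param init_low optional precomputed frozen-switch steady state
#' @return p_s threshold (nM)
#' @export
background_threshold <- function(mutated = character(),
                                 host = host_params(h_ext = 5600),
                                 punisher = punisher_params(),
                                 init_low = NULL) {
  sc <- assemble_scenario("single_burdensome_gene_with_punisher",
                          host = host, punisher = punisher,
                          mutated = mutated, freeze_switch = TRUE,
                          freeze_excision = TRUE)
  ss <- if (is.null(init_low)) steady_state(sc, horizon = 100) else
    steady_state(sc, init = init_low, horizon = 20)
  bs <- burden_summary(sc, ss)
  fp <- tryCatch(find_fixed_points(bs$Xi, punisher, bs, host),
                 error = function(e) NULL)
  saddle <- if (is.null(fp)) numeric(0) else fp$p_s[!fp$stable]
  if (length(saddle) > 0) return(max(saddle))
  high <- if (is.null(fp) || !any(fp$stable)) p_s_cap(bs, host, punisher) else
    max(fp$p_s[fp$stable])
  sqrt(max(ss$state[["p_s"]], 1) * high)
}

#' Resolve the population-model properties of one state
#'
#' @param state a label (e.g. "B\u2032SPC:H") or 0-based linear index
#' @param lib library from [single_cell_library]
#' @param punisher `punisher_params` (for the excision rate)
#' @return list(d, p_b, excision_rate, decay_rate, mapped_from)
#' @export
resolve_cell_properties <- function(state, lib, punisher = punisher_params()) {
  r <- if (is.character(state)) which(lib$label ==
         gsub("'", "\u2032", state)) else which(lib$index == state)
  if (length(r) != 1) stop("missing library entry for state: ", state)
  ex <- if (lib$C[r]) excision_activity_rate(lib$p_i[r], lib$lambda[r],
                                             punisher) else 0
  list(d = lib$lambda[r], p_b = lib$p_b[r], excision_rate = ex,
       decay_rate = lib$decay_rate[r], mapped_from = lib$mapped_from[r])
}

# effective excision rate of a cell: strand exchange gated by integrase
# activity, committed by the conformation change in competition with
# back-exchange and dilution
excision_activity_rate <- function(p_i, lambda, pp) {
  act <- p_i^4 / (pp$K_bI^4 + p_i^4)
  pp$k_sx_f * act * pp$k_conf / (pp$k_sx_b + pp$k_conf + lambda)
}

#' Estimate the Punisher transition-rate table for the population model
#'
#' For every genetic state with a functional switch unit, runs the hybrid
#' stochastic simulator (one ensemble per state) and estimates the L to H
#' activation rate from first-passage times of the switch protein across the
#' saddle; the H to L rate is estimated from the same ensemble's
#' post-activation exposure (down-crossings after activation). For states
#' with the switch unit mutated, the L to 0 and H to 0 decay rates are the
#' deterministic protease + dilution removal rate from the library.
#'
#' @param lib library from [single_cell_library]
#' @param config `stochastic_config` for the ensembles (the horizon bounds
#'   the exposure used for zero-event upper confidence limits)
#' @param host,punisher parameters matching `lib`
#' @return data.frame keyed by (genetic_state, from, to): rate, ci_low,
#'   ci_high, n_events, method
#' @export
transition_rate_table <- function(lib,
                                  config = stochastic_config(
                                    n_trajectories = 200, horizon = 20),
                                  host = host_params(h_ext = 5600),
                                  punisher = punisher_params()) {
  rows <- list()
  add <- function(gs, from, to, est, method) {
    rows[[length(rows) + 1]] <<- data.frame(
      genetic_state = gs, from = from, to = to, rate = est$rate,
      ci_low = est$ci_low, ci_high = est$ci_high, n_events = est$n_events,
      method = method, stringsAsFactors = FALSE)
  }
  gstates <- unique(lib[lib$punisher == "L",
                        c("B", "S", "P", "C", "label")])
  for (r in seq_len(nrow(gstates))) {
    gs <- sub(":L$", "", gstates$label[r])
    mut <- genetic_mutated(gstates$B[r], gstates$S[r], gstates$P[r],
                           gstates$C[r])
    if (gstates$S[r]) {
      est <- estimate_transition_rates(mut, config, host = host,
                                       punisher = punisher, from = "L")
      add(gs, "L", "H", est, "stochastic_first_passage")
      add(gs, "H", "L", est$reverse, "stochastic_post_activation")
    } else {
      row_L <- which(lib$label == paste0(gs, ":L"))
      row_H <- which(lib$label == paste0(gs, ":H"))
      add(gs, "L", "0", list(rate = lib$decay_rate[row_L], ci_low = NA,
                             ci_high = NA, n_events = NA), "deterministic")
      add(gs, "H", "0", list(rate = lib$decay_rate[row_H], ci_low = NA,
                             ci_high = NA, n_events = NA), "deterministic")
    }
  }
  do.call(rbind, rows)
}

#' Assemble the population rate matrices
#'
#' Builds the three 48 x 48 matrices of the population balance
#' xdot = (D + A + T - L) x:
#' \itemize{
#'  \item D: division with mutation. Each division produces two daughters;
#'    every still-functional unit mutates independently with probability mu,
#'    so D = 2 d P - diag(d) where P(j -> i) is the product of per-unit
#'    mutation/retention probabilities. Columns sum to d_j for any mu.
#'  \item A: integrase action, moving C to C-excised at each state's
#'    effective excision rate (zero for states without integrase protein).
#'  \item T: Punisher-coordinate transitions from the rate table.
#' }
#'
#' @param lib library from [single_cell_library]
#' @param rates table from [transition_rate_table]
#' @param mu per-unit per-division mutation probability
#' @param punisher `punisher_params`
#' @return list(D, A, T, d, p_b, states)
#' @export
build_matrices <- function(lib, rates, mu = 1e-12,
                           punisher = punisher_params()) {
  if (mu < 0 || mu > 1) stop("mu must lie in [0,1]")
  if (any(rates$rate < 0)) stop("negative transition rate")
  st <- lib
  n <- 48
  d <- st$lambda
  p_b <- st$p_b
  idx <- function(B, S, P, C, q)
    which(st$B == B & st$S == S & st$P == P & st$C == C & st$punisher == q)

  D <- matrix(0, n, n)
  units <- c("B", "S", "P", "C")
  for (j in seq_len(n)) {
    func <- units[vapply(units, function(u) st[[u]][j], logical(1))]
    subs <- if (length(func)) {
      do.call(expand.grid, setNames(rep(list(c(FALSE, TRUE)), length(func)),
                                    func))
    } else data.frame(row.names = 1)
    for (r in seq_len(nrow(subs))) {
      newly <- if (ncol(subs)) func[unlist(subs[r, , drop = TRUE])] else
        character(0)
      prob <- mu^length(newly) * (1 - mu)^(length(func) - length(newly))
      g <- setNames(st[j, units], units)
      g[newly] <- FALSE
      i <- idx(g$B, g$S, g$P, g$C, st$punisher[j])
      D[i, j] <- D[i, j] + 2 * d[j] * prob
    }
    D[j, j] <- D[j, j] - d[j]
  }

  A <- matrix(0, n, n)
  for (j in which(st$C)) {
    a <- excision_activity_rate(st$p_i[j], d[j], punisher)
    i <- idx(st$B[j], st$S[j], st$P[j], FALSE, st$punisher[j])
    A[i, j] <- A[i, j] + a
    A[j, j] <- A[j, j] - a
  }

  T_ <- matrix(0, n, n)
  for (r in seq_len(nrow(rates))) {
    gs <- rates$genetic_state[r]
    j <- which(st$label == paste0(gs, ":", rates$from[r]))
    i <- which(st$label == paste0(gs, ":", rates$to[r]))
    T_[i, j] <- T_[i, j] + rates$rate[r]
    T_[j, j] <- T_[j, j] - rates$rate[r]
  }

  list(D = D, A = A, T = T_, d = d, p_b = p_b, states = st$label)
}

#' Turbidostat dilution rate
#'
#' L = sum(x * d) / sum(x): the population-average division rate, so total
#' cell count stays constant.
#' @param x state counts (48-vector, or any length matching d)
#' @param d division rates
#' @export
dilution <- function(x, d) {
  if (sum(x) <= 0) stop("dilution: empty reactor")
  sum(x * d) / sum(x)
}

#' Full population model
#'
#' Convenience constructor: computes (or reuses) the single-cell library,
#' estimates the transition-rate table, and assembles the matrices.
#' @param host,punisher parameters
#' @param mu mutation probability per unit per division
#' @param t_cult culture duration (h)
#' @param config `stochastic_config` for rate estimation
#' @param lib,rates precomputed library / rate table (optional)
#' @return object of class `population_model`
#' @export
population_model <- function(host = host_params(h_ext = 5600),
                             punisher = punisher_params(),
                             mu = 1e-12, t_cult = 500,
                             config = stochastic_config(
                               n_trajectories = 200, horizon = 20),
                             lib = NULL, rates = NULL) {
  if (is.null(lib)) lib <- single_cell_library(host, punisher)
  if (is.null(rates))
    rates <- transition_rate_table(lib, config, host, punisher)
  m <- build_matrices(lib, rates, mu, punisher)
  m$lib <- lib
  m$rates <- rates
  m$mu <- mu
  m$t_cult <- t_cult
  m$host <- host
  m$punisher <- punisher
  class(m) <- c("population_model", "list")
  m
}

#' Initial population
#'
#' "punisher": all cells unmutated with the Punisher low (BSPC:L).
#' "control": all cells carrying the burdensome gene and CAT but no
#' switch/integrase/protease (BS\u2032P\u2032C:0).
#' @param model `population_model` (for state ordering)
#' @param type "punisher" or "control"
#' @param n total cell count
#' @export
population_init <- function(model, type = c("punisher", "control"),
                            n = 1e9) {
  type <- match.arg(type)
  lbl <- if (type == "punisher") state_label(TRUE, TRUE, TRUE, TRUE, "L")
         else state_label(TRUE, FALSE, FALSE, TRUE, "0")
  x <- setNames(numeric(48), model$states)
  x[lbl] <- n
  x
}

#' Simulate the turbidostat population
#'
#' Integrates xdot = (D + A + T) x - L(x, d) x.
#' @param model `population_model`
#' @param x0 initial 48-vector (defaults to the Punisher population)
#' @param t_cult culture duration (h)
#' @param dt output step (h)
#' @return data.frame: time, the 48 state counts (labelled columns) and Theta
#' @export
simulate_population <- function(model, x0 = population_init(model),
                                t_cult = model$t_cult, dt = 0.5) {
  if (any(x0 < 0)) stop("x0 must be non-negative")
  M <- model$D + model$A + model$T
  d <- model$d
  rhs <- function(t, x, parms) {
    x <- pmax(x, 0)
    L <- sum(x * d) / sum(x)
    list(as.vector(M %*% x) - L * x)
  }
  out <- deSolve::ode(y = setNames(as.numeric(x0), model$states),
                      times = seq(0, t_cult, by = dt), func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-10 * sum(x0))
  if (attr(out, "istate")[1] < 0)
    stop("simulate_population: integration failed (istate ",
         attr(out, "istate")[1], ")")
  df <- as.data.frame(out)
  names(df) <- c("time", model$states)
  X <- pmax(as.matrix(df[, -1]), 0)
  df$Theta <- as.vector(X %*% (d * model$p_b)) / rowSums(X)
  df
}

#' Population productivity metrics
#'
#' Theta(t): population-average burdensome-protein production rate per cell,
#' sum(x_j d_j p_b(j)) / sum(x_j). Y: its time integral over the culture.
#' tau: total duration for which Theta stays above 50% of its maximum.
#' @param traj trajectory from [simulate_population]
#' @param model `population_model`
#' @return list(Theta = data.frame(time, Theta), Y, tau)
#' @export
productivity_metrics <- function(traj, model) {
  t <- traj$time
  th <- traj$Theta
  dt <- diff(t)
  Y <- sum(dt * (th[-1] + th[-length(th)]) / 2)
  half <- max(th) / 2
  above <- th >= half
  tau <- sum(dt * (above[-1] & above[-length(above)])) +
    sum(dt / 2 * xor(above[-1], above[-length(above)]))
  list(Theta = data.frame(time = t, Theta = th), Y = Y, tau = tau)
}

#' Sweep the mutation probability
#'
#' Re-assembles the division matrix for each mu (library and transition rates
#' are mu-independent) and reports Y and tau for the Punisher population and
#' the no-Punisher control.
#' @param model `population_model`
#' @param mus mutation probabilities to scan
#' @param t_cult culture duration (h)
#' @return data.frame(mu, Y_punisher, tau_punisher, Y_control, tau_control)
#' @export
sweep_mu <- function(model, mus, t_cult = model$t_cult) {
  res <- lapply(mus, function(mu) {
    m <- build_matrices(model$lib, model$rates, mu,
                        punisher = model$punisher)
    m <- utils::modifyList(model, m)
    pm <- productivity_metrics(
      simulate_population(m, population_init(m, "punisher"), t_cult), m)
    cm <- productivity_metrics(
      simulate_population(m, population_init(m, "control"), t_cult), m)
    data.frame(mu = mu, Y_punisher = pm$Y, tau_punisher = pm$tau,
               Y_control = cm$Y, tau_control = cm$tau)
  })
  do.call(rbind, res)
}
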