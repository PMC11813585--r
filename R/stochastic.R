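#' Configuration for hybrid stochastic simulation
#'
#' @param seed integer RNG seed
#' @param n_trajectories ensemble size
#' @param tau leap interval (h)
#' @param horizon simulation end time (h)
#' @param discrete species treated stochastically (jumping by integer
#'   molecule counts); the remainder follows the deterministic rates
#' @param vol conversion factor between nM and molecule counts
#'   (molecules per nM; ~0.6 for an E. coli-sized cell)
#' @param record_dt recording interval (h)
#' @export
stochastic_config <- function(seed = 1, n_trajectories = 200, tau = 0.01,
                              horizon = 50,
                              discrete = c("m_s", "p_s", "p_i",
                                           "dna_cat", "dna_LRi"),
                              vol = NM_TO_COUNT, record_dt = 0.25) {
  if (tau <= 0) stop("tau must be > 0")
  if (n_trajectories < 1) stop("n_trajectories must be >= 1")
  if (vol <= 0) stop("vol must be > 0")
  cfg <- list(seed = as.integer(seed), n_trajectories = n_trajectories,
              tau = tau, horizon = horizon, discrete = discrete, vol = vol,
              record_dt = record_dt)
  class(cfg) <- c("stochastic_config", "list")
  cfg
}

# vectorised QSSA partition of total tRNA into charged/uncharged:
# nu(t_u)*p_a = eps(t_c)*B at fixed total T (charging equilibrates much
# faster than the pool size changes); bisection on t_c in [0, T]
solve_tc <- function(T_tot, p_a, B, hp) {
  lo <- rep(0, length(T_tot)); hi <- T_tot
  g <- function(tc) {
    tu <- T_tot - tc
    hp$nu_max * hp$sigma * tu / (tu + hp$K_nu) * p_a -
      hp$eps_max * tc / (tc + hp$K_eps) * B
  }
  for (i in 1:50) {
    mid <- 0.5 * (lo + hi)
    pos <- g(mid) > 0
    lo <- ifelse(pos, mid, lo)
    hi <- ifelse(pos, hi, mid)
  }
  0.5 * (lo + hi)
}

#' Hybrid tau-leaping simulation of a Punisher scenario
#'
#' Simulates an ensemble of single cells. Low-copy circuit species (by
#' default the switch mRNA, switch and integrase proteins and the CAT DNA
#' states) jump by integer molecule counts: births are Poisson within each
#' leap, removals are binomial thinnings (so counts can never go negative),
#' and DNA state changes are per-copy binomial draws. High-copy species
#' follow the deterministic mass balances by explicit stepping, with the fast
#' tRNA-charging and chloramphenicol balances resolved by quasi-steady state
#' within each leap. A step producing a negative continuous state is rejected
#' and retried at half the leap size.
#'
#' Supported scenarios: host plus constitutive synthetic genes, with or
#' without the Punisher (no co-expression topologies).
#'
#' @param sc a `scenario`
#' @param config a `stochastic_config`
#' @param init named initial state in nM (e.g. from [punisher_low_init])
#' @param record species to record (in nM), plus "lambda"
#' @return list: times, one (n_trajectories x n_times) matrix per recorded
#'   quantity, and `final` (matrix of final states in nM)
#' @export
simulate_hybrid <- function(sc, config, init,
                            record = c("p_s", "lambda")) {
  if (!is.null(sc$coexpression))
    stop("simulate_hybrid does not support co-expression topologies")
  for (g in names(sc$genes))
    if (sc$genes[[g]]$regulation$type != "constitutive")
      stop("simulate_hybrid supports constitutive synthetic genes only")
  set.seed(config$seed)
  hp <- sc$host
  pun <- sc$punisher
  n <- config$n_trajectories
  vol <- config$vol

  species <- names(init)
  Y <- matrix(rep(as.numeric(init), each = n), nrow = n,
              dimnames = list(NULL, species))
  # total tRNA replaces the fast charged/uncharged pair
  T_tot <- Y[, "t_c"] + Y[, "t_u"]
  disc <- intersect(config$discrete, species)
  # discrete species stored as integer counts
  cnt <- list()
  for (s in disc) cnt[[s]] <- round(Y[, s] * vol)

  val <- function(s) if (s %in% disc) cnt[[s]] / vol else Y[, s]

  times <- seq(0, config$horizon, by = config$record_dt)
  rec <- lapply(record, function(r)
    matrix(NA_real_, n, length(times)))
  names(rec) <- record
  rec_i <- 1

  genes <- sc$genes
  mut <- sc$mutated
  eps_prev <- rep(hp$eps_max / 2, n)
  lam_prev <- rep(1, n)
  t_now <- 0
  tau0 <- config$tau

  step_rates <- function() {
    p_a <- Y[, "p_a"]; R <- Y[, "R"]
    p_prot <- if (!is.null(pun)) val("p_prot") else rep(0, n)
    mk <- Y[, "m_a"] / hp$k_a + Y[, "m_r"] / hp$k_r
    for (g in names(genes)) mk <- mk + val(paste0("m_", g)) / genes[[g]]$k_x
    delta <- rep(0, n)
    m_i_nm <- NULL
    if (!is.null(pun)) {
      gs <- pun$genes$s; gi <- pun$genes$i
      m_s_nm <- val("m_s")
      m_i_nm <- m_s_nm * gi$n_x / gs$n_x
      mk <- mk + m_s_nm / gs$k_x + m_i_nm / gi$k_x +
        val("m_prot") / pun$genes$prot$k_x + val("m_cat") / pun$genes$cat$k_x
      delta <- p_prot * (gs$n_x * gs$delta_x * val("p_s") +
                         gi$n_x * gi$delta_x * val("p_i"))
    }
    # chloramphenicol QSS given CAT level and lagged growth rate
    p_cat <- if (!is.null(pun)) val("p_cat") else rep(0, n)
    h <- hp$kappa * hp$h_ext / (hp$kappa + p_cat / sc$K_C + lam_prev)
    q <- (hp$K_D + h) / hp$K_D
    # D with lagged eps in the (small) protease correction
    dER <- ifelse(delta > 0, delta / (eps_prev * R), 0)
    den <- 1 - hp$phi_q * (1 - q * dER)
    D <- q * (1 + mk - q * hp$phi_q * dER / den)
    B <- R * mk / D
    t_c <- solve_tc(T_tot, p_a, B, hp)
    t_u <- T_tot - t_c
    eps <- hp$eps_max * t_c / (t_c + hp$K_eps)
    lam <- eps * B / ((1 - hp$phi_q) * hp$M)
    F_r <- ifelse(t_c + t_u > 0, t_c / (t_c + hp$tau_ppGpp * t_u), 0)
    nu <- hp$nu_max * hp$sigma * t_u / (t_u + hp$K_nu)
    list(mk = mk, D = D, B = B, t_c = t_c, t_u = t_u, eps = eps, lam = lam,
         F_r = F_r, nu = nu, psi = hp$psi_max * F_r, h = h,
         p_prot = p_prot, delta = delta)
  }

  rt0 <- step_rates()
  eps_prev <- rt0$eps; lam_prev <- rt0$lam
  for (r in record)
    rec[[r]][, 1] <- if (r == "lambda") lam_prev else val(r)
  rec_i <- 2

  while (t_now < config$horizon - 1e-12) {
    tau <- min(tau0, config$horizon - t_now)
    repeat {
      rt <- step_rates()
      lam <- rt$lam; eps <- rt$eps; D <- rt$D; R <- Y[, "R"]
      Y2 <- Y
      # host continuous updates
      Y2[, "m_a"] <- Y[, "m_a"] + tau *
        (hp$c_a * hp$alpha_a * lam - (hp$beta_a + lam) * Y[, "m_a"])
      Y2[, "m_r"] <- Y[, "m_r"] + tau *
        (rt$F_r * hp$c_r * hp$alpha_r * lam - (hp$beta_r + lam) * Y[, "m_r"])
      Y2[, "p_a"] <- Y[, "p_a"] + tau *
        (eps / hp$n_a * (Y[, "m_a"] / hp$k_a) / D * R - lam * Y[, "p_a"])
      Y2[, "R"] <- R + tau *
        (eps / hp$n_r * (Y[, "m_r"] / hp$k_r) / D * R - lam * R)
      T2 <- T_tot + tau * lam * (rt$psi - T_tot)
      # regular synthetic genes (continuous)
      for (g in names(genes)) {
        gg <- genes[[g]]
        cg <- if (g %in% mut) 0 else gg$c_x
        mg <- paste0("m_", g); pg <- paste0("p_", g)
        Y2[, mg] <- Y[, mg] + tau *
          (cg * gg$alpha_x * lam - (gg$beta_x + lam) * Y[, mg])
        Y2[, pg] <- Y[, pg] + tau *
          (eps / gg$n_x * (Y[, mg] / gg$k_x) / D * R -
             (gg$delta_x * rt$p_prot + lam) * Y[, pg])
      }
      cnt2 <- cnt
      if (!is.null(pun)) {
        gs <- pun$genes$s; gi <- pun$genes$i
        gp <- pun$genes$prot; gc <- pun$genes$cat
        c_s <- if ("s" %in% mut) 0 else gs$c_x
        c_p <- if ("prot" %in% mut) 0 else gp$c_x
        F_s <- if (isTRUE(sc$freeze_switch)) rep(pun$F_sb, n) else
          switch_regulation(val("p_s"), pun)
        upd <- function(sp, birth, death_rate) {
          # birth in nM/h, death_rate in 1/h
          if (sp %in% disc) {
            x <- cnt[[sp]]
            b <- stats::rpois(n, pmax(birth, 0) * vol * tau)
            d <- stats::rbinom(n, x, 1 - exp(-pmax(death_rate, 0) * tau))
            cnt2[[sp]] <<- x + b - d
          } else {
            Y2[, sp] <<- Y[, sp] + tau * (birth - death_rate * Y[, sp])
          }
        }
        m_s <- val("m_s")
        upd("m_s", F_s * c_s * gs$alpha_x * lam, gs$beta_x + lam)
        upd("p_s", eps / gs$n_x * (m_s / gs$k_x) / D * R,
            gs$delta_x * rt$p_prot + lam)
        m_i <- m_s * gi$n_x / gs$n_x
        upd("p_i", eps / gi$n_x * (m_i / gi$k_x) / D * R,
            gi$delta_x * rt$p_prot + lam)
        upd("m_prot", c_p * gp$alpha_x * lam, gp$beta_x + lam)
        upd("p_prot", eps / gp$n_x * (val("m_prot") / gp$k_x) / D * R, lam)
        upd("m_cat", val("dna_cat") * gc$alpha_x * lam, gc$beta_x + lam)
        upd("p_cat", eps / gc$n_x * (val("m_cat") / gc$k_x) / D * R, lam)
        # DNA states: per-copy transitions
        fwd_rate <- pun$k_sx_f * val("p_i")^4 / (pun$K_bI^4 + val("p_i")^4)
        if ("dna_cat" %in% disc) {
          x_cat <- cnt[["dna_cat"]]; x_lri <- cnt[["dna_LRi"]]
          go <- stats::rbinom(n, x_cat, 1 - exp(-fwd_rate * tau))
          p_b <- 1 - exp(-pun$k_sx_b * tau)
          p_c <- 1 - exp(-(pun$k_conf + lam) * tau)
          back <- stats::rbinom(n, x_lri, p_b)
          # conformation/dilution competes with back-exchange; thin remainder
          conf <- stats::rbinom(n, x_lri - back,
                                pmin(1, p_c / pmax(1 - p_b, 1e-12)))
          cnt2[["dna_cat"]] <- x_cat - go + back
          cnt2[["dna_LRi"]] <- x_lri + go - back - conf
        } else {
          fwd <- fwd_rate * Y[, "dna_cat"]
          bck <- pun$k_sx_b * Y[, "dna_LRi"]
          Y2[, "dna_cat"] <- Y[, "dna_cat"] + tau * (-fwd + bck)
          Y2[, "dna_LRi"] <- Y[, "dna_LRi"] + tau *
            (fwd - bck - (pun$k_conf + lam) * Y[, "dna_LRi"])
        }
      }
      if ("h" %in% species) Y2[, "h"] <- rt$h
      Y2[, "t_c"] <- rt$t_c; Y2[, "t_u"] <- rt$t_u
      cont_cols <- setdiff(species, disc)
      if (all(Y2[, cont_cols] > -1e-8)) {
        Y <- Y2; cnt <- cnt2; T_tot <- T2
        eps_prev <- eps; lam_prev <- lam
        break
      }
      tau <- tau / 2
      if (tau < 1e-6) stop("simulate_hybrid: leap size collapsed")
    }
    t_now <- t_now + tau
    while (rec_i <= length(times) && times[rec_i] <= t_now + 1e-9) {
      for (r in record) {
        rec[[r]][, rec_i] <- if (r == "lambda") lam_prev else val(r)
      }
      rec_i <- rec_i + 1
    }
  }
  final <- Y
  for (s in disc) final[, s] <- cnt[[s]] / vol
  c(list(times = times, final = final), rec)
}

#' Exponential rate estimate from event counts and exposure
#'
#' Maximum-likelihood rate n/T with an exact Poisson (gamma) confidence
#' interval; with zero events the rate is 0 and the upper bound is the
#' one-sided limit.
#' @param n_events number of observed transition events
#' @param exposure total time at risk (h)
#' @param level confidence level
#' @export
rate_estimate <- function(n_events, exposure, level = 0.95) {
  if (exposure <= 0) stop("exposure must be positive")
  a <- (1 - level) / 2
  rate <- n_events / exposure
  ci_low <- if (n_events == 0) 0 else stats::qgamma(a, n_events) / exposure
  ci_high <- stats::qgamma(if (n_events == 0) level else 1 - a,
                           n_events + 1) / exposure
  list(rate = rate, ci_low = ci_low, ci_high = ci_high,
       n_events = n_events, flagged = n_events == 0)
}

#' Estimate Punisher state-transition rates for a genetic background
#'
#' Runs the hybrid simulator from the low- (or high-) expression state of the
#' given genetic background and converts first-passage times of the switch
#' protein across the unstable fixed point (with a +/-10% hysteresis band)
#' into exponential transition rates. Backgrounds whose low-expression
#' equilibrium does not exist yield fast "true positive" rates; backgrounds
#' with an existing low equilibrium yield small "false positive" rates, often
#' zero events (reported as rate 0 with a one-sided upper bound, flagged).
#'
#' @param genetic_state character vector of mutated genes among
#'   c("b", "s", "prot", "cat") (empty = fully functional)
#' @param config a `stochastic_config`
#' @param host `host_params`
#' @param punisher `punisher_params`
#' @param from start state, "L" or "H"
#' @param p_threshold p_s level separating the low and high basins; computed
#'   per background via [background_threshold] when NULL
#' @return list of class `transition_rate_estimate`: from, to, rate, ci_low,
#'   ci_high, n_events, plus the first-passage times
#' @export
estimate_transition_rates <- function(genetic_state = character(),
                                      config = stochastic_config(),
                                      host = host_params(h_ext = 5600),
                                      punisher = punisher_params(),
                                      from = "L",
                                      p_threshold = NULL) {
  if ("s" %in% genetic_state && from != "0")
    return(list(from = from, to = if (from == "L") "H" else "L",
                rate = 0, ci_low = 0, ci_high = 0, n_events = 0,
                flagged = FALSE, fpt = numeric(0),
                reverse = list(rate = 0, ci_low = 0, ci_high = 0,
                               n_events = 0, flagged = FALSE)))
  sc <- assemble_scenario("single_burdensome_gene_with_punisher",
                          host = host, punisher = punisher,
                          mutated = genetic_state)
  init <- punisher_low_init(sc)
  if (is.null(p_threshold))
    p_threshold <- background_threshold(genetic_state, host, punisher,
                                        init_low = init)
  if (from == "H") {
    init["p_s"] <- p_threshold * 10
    init["p_i"] <- p_threshold * 2.5
  }
  res <- simulate_hybrid(sc, config, init, record = "p_s")
  up <- p_threshold * 1.1
  down <- p_threshold * 0.9
  crossed <- if (from == "L") res$p_s > up else res$p_s < down
  first_cross <- function(z) {
    i <- which(z)[1]
    if (is.na(i)) NA_real_ else res$times[i]
  }
  fpt <- apply(crossed, 1, first_cross)
  n_ev <- sum(!is.na(fpt))
  exposure <- sum(ifelse(is.na(fpt), config$horizon, fpt))
  est <- rate_estimate(n_ev, exposure)
  # reverse transition: first passage back across the opposite hysteresis
  # bound, using the post-activation segments of the same ensemble
  rev_crossed <- if (from == "L") res$p_s < down else res$p_s > up
  rev_fpt <- vapply(seq_along(fpt), function(k) {
    if (is.na(fpt[k])) return(NA_real_)
    seg <- rev_crossed[k, ] & res$times > fpt[k]
    first_cross(seg)
  }, numeric(1))
  rev_exposure <- sum(ifelse(is.na(fpt), 0,
                             ifelse(is.na(rev_fpt), config$horizon,
                                    rev_fpt) - fpt))
  rev_est <- if (rev_exposure > 0)
    rate_estimate(sum(!is.na(rev_fpt)), rev_exposure)
  else list(rate = 0, ci_low = 0, ci_high = Inf, n_events = 0, flagged = TRUE)
  c(list(from = from, to = if (from == "L") "H" else "L", fpt = fpt,
         reverse = rev_est), est)
}

#' Simulate a two-state telegraph process exactly
#'
#' Benchmark generator for the transition-rate estimator: alternating
#' exponential sojourns in states 0/1 with rates k_on (0 to 1) and k_off.
#' @param k_on,k_off transition rates (1/h)
#' @param horizon total simulated time (h)
#' @param seed RNG seed
#' @return data.frame(state, dwell) of completed sojourns
#' @export
simulate_telegraph <- function(k_on, k_off, horizon = 1000, seed = 1) {
  set.seed(seed)
  t <- 0; s <- 0L
  states <- integer(0); dwells <- numeric(0)
  while (t < horizon) {
    rate <- if (s == 0L) k_on else k_off
    d <- stats::rexp(1, rate)
    if (t + d > horizon) break
    states <- c(states, s); dwells <- c(dwells, d)
    s <- 1L - s; t <- t + d
  }
  data.frame(state = states, dwell = dwells)
}

#' Estimate telegraph rates from sojourn data
#' @param sojourns data.frame from [simulate_telegraph]
#' @return list(k_on, k_off) with exponential-MLE estimates and CIs
#' @export
estimate_telegraph_rates <- function(sojourns) {
  est <- function(d) rate_estimate(length(d), sum(d))
  list(k_on = est(sojourns$dwell[sojourns$state == 0L]),
       k_off = est(sojourns$dwell[sojourns$state == 1L]))
}
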