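#' Steady-state burden of expressing a gene
#'
#' xi_j = F_j * alpha_j * c_j / k_j: the gene's share of translational demand.
#' The effective dissociation constant is taken as the gene's k_j; since only
#' burden ratios enter the switching analysis and mRNA degradation rates are
#' comparable across genes, a common normalisation cancels.
#'
#' @param F_bar steady-state transcription regulation value in \[0,1\]
#' @param alpha promoter strength
#' @param c gene DNA concentration (nM)
#' @param k_bar effective mRNA-ribosome dissociation constant (nM, > 0)
#' @export
gene_burden <- function(F_bar, alpha, c, k_bar) {
  if (any(k_bar <= 0)) stop("gene_burden: k_bar must be > 0")
  if (any(c(F_bar, alpha, c) < 0)) stop("gene_burden: inputs must be >= 0")
  F_bar * alpha * c / k_bar
}

#' Total burden sensed by the Punisher
#'
#' Sum of per-gene burdens over all native and synthetic genes except the
#' Punisher's switch and integrase.
#' @param xi named vector of per-gene burdens
#' @export
total_burden <- function(xi) {
  sum(xi[setdiff(names(xi), c("s", "i"))])
}

#' Burden summary of a genetic background
#'
#' Computes per-gene burdens xi_j at the steady state of a scenario, the total
#' burden Xi (excluding switch and integrase), the maximal switch/integrase
#' burdens (at F_s = 1) and the protease correction factor chi. Steady-state
#' regulation values (F_r for the ribosomal gene, toggle repression values)
#' and the steady-state elongation rate and intracellular chloramphenicol
#' feeding chi are taken from the supplied steady state.
#'
#' chi quantifies protease degradation of the switch relative to dilution:
#' chi = (K_D + h_bar)/K_D * delta_s * (1-phi_q) * M * n_r * xi_prot /
#'       (eps_bar * n_prot * xi_r).
#'
#' @param sc a `scenario` (must carry `punisher` for xi_s_max/xi_i_max/chi)
#' @param ss result of [steady_state] for the relevant genetic background; if
#'   NULL it is computed
#' @param punisher `punisher_params` to use when the background scenario
#'   itself lacks the Punisher (e.g. burden computed for a control topology)
#' @return list of class `burden_summary`: xi (named vector), Xi, xi_s_max,
#'   xi_i_max, chi, eps_bar, h_bar, lambda_bar
#' @export
burden_summary <- function(sc, ss = NULL, punisher = sc$punisher) {
  if (is.null(ss)) ss <- steady_state(sc)
  hp <- sc$host
  st <- ss$state
  rt <- ss$rates
  xi <- c(a = gene_burden(1, hp$alpha_a, hp$c_a, hp$k_a),
          r = gene_burden(rt[["F_r"]], hp$alpha_r, hp$c_r, hp$k_r))
  for (g in names(sc$genes)) {
    gene <- sc$genes[[g]]
    reg <- gene$regulation
    F_bar <- switch(reg$type,
      constitutive = 1,
      toggle_repression = toggle_regulation(st[[paste0("p_", reg$partner)]],
                                            reg, 0))
    xi[g] <- gene_burden(F_bar, gene$alpha_x, effective_c(gene, sc$mutated),
                         gene$k_x)
  }
  if (!is.null(sc$coexpression)) {
    k_co <- (sc$coexpression$k_off + rt[["eps"]] / sc$coexpression$n_cat) /
      sc$coexpression$k_plus
    for (g in names(sc$genes)) {
      mult <- xi[[g]] * sc$genes[[g]]$k_x / k_co
      xi[paste0("cat_", g)] <- mult
    }
  }
  pp <- punisher
  xi_s_max <- xi_i_max <- chi <- NA_real_
  if (!is.null(pp)) {
    gs <- pp$genes$s; gi <- pp$genes$i
    gpr <- pp$genes$prot; gct <- pp$genes$cat
    xi_s_max <- gene_burden(1, gs$alpha_x, gs$c_x, gs$k_x)
    # integrase shares the switch transcript; demand scales with n_i/n_s
    xi_i_max <- gene_burden(1, gi$alpha_x, gi$c_x, gi$k_x) * gi$n_x / gs$n_x
    if (!is.null(sc$punisher)) {
      xi["prot"] <- gene_burden(1, gpr$alpha_x,
                                effective_c(gpr, sc$mutated), gpr$k_x)
      xi["cat"] <- gene_burden(1, gct$alpha_x, st[["dna_cat"]], gct$k_x)
    }
    h_bar <- st[["h"]]
    eps_bar <- rt[["eps"]]
    chi <- (hp$K_D + h_bar) / hp$K_D * gs$delta_x * (1 - hp$phi_q) * hp$M *
      hp$n_r * xi[["prot"]] / (eps_bar * gpr$n_x * xi[["r"]])
  }
  out <- list(xi = xi, Xi = total_burden(xi),
              xi_s_max = xi_s_max, xi_i_max = xi_i_max, chi = chi,
              eps_bar = rt[["eps"]], h_bar = st[["h"]],
              lambda_bar = rt[["lambda"]])
  class(out) <- c("burden_summary", "list")
  out
}

#' Required switch regulation value
#'
#' The value of F_s needed to hold the switch protein at concentration p_s
#' given total burden Xi:
#' F_s_req = p_s*(1+chi) * Xi/(xi_s_max + xi_i_max) *
#'   (M*(1-phi_q)/n_s * xi_s_max/(xi_s_max + xi_i_max) - p_s*(1+chi))^-1.
#' Returns NA (with a warning when `strict = FALSE`) or signals an error when
#' p_s exceeds the physically attainable concentration (bracket <= 0).
#'
#' @param p_s target switch protein concentration (nM), scalar or vector
#' @param Xi total burden (excluding switch and integrase)
#' @param bs `burden_summary`
#' @param host `host_params`
#' @param pp `punisher_params` (for n_s)
#' @param strict error (TRUE) or NA (FALSE) on unreachable p_s
#' @export
required_regulation <- function(p_s, Xi, bs, host, pp, strict = TRUE) {
  if (any(p_s < 0)) stop("required_regulation: p_s must be >= 0")
  xi_si <- bs$xi_s_max + bs$xi_i_max
  cap <- host$M * (1 - host$phi_q) / pp$genes$s$n_x * bs$xi_s_max / xi_si
  bracket <- cap - p_s * (1 + bs$chi)
  bad <- bracket <= 0
  if (any(bad) && strict)
    stop("required_regulation: p_s unreachable (bracket <= 0)")
  out <- p_s * (1 + bs$chi) * Xi / xi_si / bracket
  out[bad] <- NA_real_
  out
}

#' Maximum reachable switch protein concentration
#' @keywords internal
p_s_cap <- function(bs, host, pp) {
  xi_si <- bs$xi_s_max + bs$xi_i_max
  host$M * (1 - host$phi_q) / pp$genes$s$n_x * bs$xi_s_max / xi_si /
    (1 + bs$chi)
}

#' Fixed points of the self-activating switch
#'
#' All solutions of F_s_req(p_s, Xi) = F_s_real(p_s) on (0, p_max), found by
#' sign changes of the difference on a dense log-spaced grid refined by
#' bisection. Stability follows the one-dimensional graphical criterion: p_s
#' grows where the real regulation exceeds the required one, so a fixed point
#' is stable when real - required changes sign from + to -.
#'
#' @param Xi total burden
#' @param pp `punisher_params`
#' @param bs `burden_summary`
#' @param host `host_params`
#' @param n_grid grid resolution
#' @return data.frame(p_s, F_s, stable) sorted ascending in p_s
#' @export
find_fixed_points <- function(Xi, pp, bs, host, n_grid = 4000) {
  cap <- p_s_cap(bs, host, pp)
  grid <- exp(seq(log(1e-3), log(cap * 0.999999), length.out = n_grid))
  g <- switch_regulation(grid, pp) -
    required_regulation(grid, Xi, bs, host, pp)
  sgn <- sign(g)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- vapply(idx, function(i) {
    uniroot(function(p) switch_regulation(p, pp) -
              required_regulation(p, Xi, bs, host, pp),
            lower = grid[i], upper = grid[i + 1], tol = 1e-10 * grid[i + 1])$root
  }, numeric(1))
  # exact zeros on grid points (rare) count as degenerate roots
  zero_idx <- which(g == 0)
  roots <- sort(unique(c(roots, grid[zero_idx])))
  stable <- vapply(roots, function(p) {
    lo <- p * (1 - 1e-4); hi <- p * (1 + 1e-4)
    gl <- switch_regulation(lo, pp) - required_regulation(lo, Xi, bs, host, pp)
    gh <- switch_regulation(hi, pp) - required_regulation(hi, Xi, bs, host, pp)
    gl > 0 && gh < 0
  }, logical(1))
  data.frame(p_s = roots, F_s = switch_regulation(roots, pp), stable = stable)
}

# does a stable low-expression equilibrium exist at burden Xi?
low_branch_exists <- function(Xi, pp, bs, host, n_grid = 4000) {
  fp <- find_fixed_points(Xi, pp, bs, host, n_grid)
  p_mid <- pp$K_s / max(pp$I, 1e-12)
  any(fp$stable & fp$p_s < p_mid)
}

#' Switching threshold burden
#'
#' The saddle-node burden value at which the switch's low-expression
#' equilibrium vanishes: for Xi > Xi_hat the low branch exists, below it only
#' the high-expression equilibrium remains. Located by bisection on the
#' low-branch existence predicate after a log-grid scan establishes that the
#' system is bistable for some Xi in `Xi_range`.
#'
#' @param pp `punisher_params`
#' @param bs `burden_summary`
#' @param host `host_params`
#' @param Xi_range burden interval scanned (default 1 to 1e4)
#' @param rel_tol relative tolerance on Xi_hat
#' @return Xi_hat, or NA with attribute `reason = "no_switching"` when the
#'   fixed-point count never changes over the scanned range
#' @export
find_threshold <- function(pp, bs, host, Xi_range = c(1, 1e4),
                           rel_tol = 1e-6) {
  scan <- exp(seq(log(Xi_range[1]), log(Xi_range[2]), length.out = 60))
  has_low <- vapply(scan, low_branch_exists, logical(1), pp = pp, bs = bs,
                    host = host, n_grid = 1500)
  n_fp <- vapply(scan, function(Xi)
    nrow(find_fixed_points(Xi, pp, bs, host, n_grid = 1500)), numeric(1))
  if (all(has_low) || !any(has_low) || !any(n_fp >= 3)) {
    out <- NA_real_
    attr(out, "reason") <- "no_switching"
    return(out)
  }
  i_hi <- min(which(has_low))           # smallest Xi with a low branch
  if (i_hi == 1) {
    out <- NA_real_
    attr(out, "reason") <- "no_switching"
    return(out)
  }
  lo <- scan[i_hi - 1]; hi <- scan[i_hi]
  while ((hi - lo) / hi > rel_tol) {
    mid <- sqrt(lo * hi)
    if (low_branch_exists(mid, pp, bs, host)) hi <- mid else lo <- mid
  }
  sqrt(lo * hi)
}

# integrase concentration associated with a switch fixed point:
# the co-expressed transcript gives p_i = p_s * k_s / k_i (equal protease
# susceptibility assumed, as in the default registry)
p_i_of_p_s <- function(p_s, pp) {
  p_s * pp$genes$s$k_x / pp$genes$i$k_x
}

# Hill(4) DNA-cutting propensity of the integrase
integrase_activity <- function(p_i, pp) {
  p_i^4 / (pp$K_bI^4 + p_i^4)
}

#' Lower bound on the integrase activity fold-change upon switching
#'
#' Ratio of the Hill(4) excision propensity at the high-expression fixed point
#' of the post-mutation burden to the propensity at the largest sub-threshold
#' fixed point (the saddle, if present) of the pre-mutation burden. Using the
#' saddle rather than the stable low fixed point makes the ratio a true lower
#' bound on the realised activity change.
#'
#' @param pp `punisher_params`
#' @param bs `burden_summary`
#' @param host `host_params`
#' @param Xi_pre,Xi_post burden before/after the mutation to be detected
#' @return fold-change bound (>= 1 when switching occurs), or NA with
#'   attribute `reason = "no_switching"`
#' @export
fold_change_bound <- function(pp, bs, host, Xi_pre, Xi_post) {
  fp_pre <- find_fixed_points(Xi_pre, pp, bs, host)
  fp_post <- find_fixed_points(Xi_post, pp, bs, host)
  p_mid <- pp$K_s / max(pp$I, 1e-12)
  low_ok <- any(fp_pre$stable & fp_pre$p_s < p_mid)
  high_post <- fp_post$p_s[fp_post$stable & fp_post$p_s >= p_mid]
  if (!low_ok || length(high_post) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "no_switching"
    return(out)
  }
  pre_candidates <- fp_pre$p_s[fp_pre$p_s < p_mid]
  p_pre <- max(pre_candidates)          # saddle when bistable
  p_high <- max(high_post)
  integrase_activity(p_i_of_p_s(p_high, pp), pp) /
    integrase_activity(p_i_of_p_s(p_pre, pp), pp)
}

#' Scan the Punisher design space
#'
#' Evaluates the switching threshold, the integrase fold-change bound and
#' acceptable-region membership (Xi_post < Xi_hat < Xi_pre) over a grid of
#' two design parameters. Scannable parameters: `c_si` (switch/integrase DNA
#' concentration, keeping c_s = c_i), `I`, `eta_s`, `inv_F_sb` (the
#' maximum-to-baseline promoter activity ratio 1/F_sb).
#'
#' @param axis1,axis2 lists `list(param = "<name>", values = <numeric>)`
#' @param pp base `punisher_params`
#' @param bs `burden_summary` of the pre-mutation background
#' @param host `host_params`
#' @param Xi_pre,Xi_post pre-/post-mutation burden
#' @return long data.frame: axis values, Xi_hat, fold_change_bound,
#'   acceptable, error (empty string when the point evaluated cleanly)
#' @export
design_space_scan <- function(axis1, axis2, pp, bs, host, Xi_pre, Xi_post) {
  set_param <- function(pp, name, value) {
    switch(name,
      c_si = { pp$genes$s$c_x <- value; pp$genes$i$c_x <- value },
      I = pp$I <- value,
      eta_s = pp$eta_s <- value,
      inv_F_sb = pp$F_sb <- 1 / value,
      stop("unscannable parameter: ", name))
    pp
  }
  grid <- expand.grid(v1 = axis1$values, v2 = axis2$values)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    ppi <- set_param(set_param(pp, axis1$param, grid$v1[i]),
                     axis2$param, grid$v2[i])
    bsi <- bs
    gs <- ppi$genes$s; gi <- ppi$genes$i
    bsi$xi_s_max <- gene_burden(1, gs$alpha_x, gs$c_x, gs$k_x)
    bsi$xi_i_max <- gene_burden(1, gi$alpha_x, gi$c_x, gi$k_x) *
      gi$n_x / gs$n_x
    out <- tryCatch({
      Xi_hat <- find_threshold(ppi, bsi, host)
      if (is.na(Xi_hat)) {
        data.frame(Xi_hat = NA_real_, fold_change_bound = NA_real_,
                   acceptable = FALSE, error = "no_switching")
      } else {
        fc <- fold_change_bound(ppi, bsi, host, Xi_pre, Xi_post)
        data.frame(Xi_hat = Xi_hat,
                   fold_change_bound = as.numeric(fc),
                   acceptable = !is.na(Xi_hat) &&
                     Xi_post < Xi_hat && Xi_hat < Xi_pre,
                   error = if (is.na(fc)) "no_switching" else "")
      }
    }, error = function(e)
      data.frame(Xi_hat = NA_real_, fold_change_bound = NA_real_,
                 acceptable = FALSE, error = conditionMessage(e)))
    cbind(stats::setNames(grid[i, , drop = FALSE],
                          c(axis1$param, axis2$param)), out)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
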