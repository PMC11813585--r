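#' Ribosomal competition denominator
#'
#' Dimensionless factor partitioning ribosomes among all mRNAs in the cell,
#' inflated by chloramphenicol-inactivated ribosomes and corrected for the
#' translation flux consumed replacing protease-degraded synthetic proteins.
#'
#' D = q * (1 + sum_j m_j/k_j - q*phi_q*Delta/(eps*R) /
#'          (1 - phi_q*(1 - q*Delta/(eps*R)))),  q = (K_D + h)/K_D,
#' where Delta = p_prot * sum_x n_x * delta_x * p_x aggregates protease
#' degradation of synthetic proteins.
#'
#' @param mk_sum sum of m_j/k_j over all native and synthetic mRNAs
#' @param h intracellular chloramphenicol (nM)
#' @param delta protease-degradation aggregate Delta (aa nM^2 / (nM h) scale)
#' @param eps translation elongation rate (aa/h); must be > 0 when delta > 0
#' @param R ribosome concentration (nM); must be > 0 when delta > 0
#' @param params host parameters (uses K_D, phi_q)
#' @return D (dimensionless, >= 1 when h = 0 and delta = 0)
#' @export
competition_denominator <- function(mk_sum, h, delta, eps, R, params) {
  if (any(c(mk_sum, h, delta, eps, R) < 0) ||
      any(!is.finite(c(mk_sum, h, delta))))
    stop("competition_denominator: inputs must be finite and non-negative")
  q <- (params$K_D + h) / params$K_D
  if (delta == 0) {
    corr <- 0
  } else {
    if (eps <= 0 || R <= 0)
      stop("competition_denominator: eps and R must be positive when delta > 0")
    dER <- delta / (eps * R)
    den <- 1 - params$phi_q * (1 - q * dER)
    if (den <= 0)
      stop("competition_denominator: phi_q bracket denominator <= 0")
    corr <- q * params$phi_q * dER / den
  }
  q * (1 + mk_sum - corr)
}

#' Protease degradation aggregate
#'
#' Delta = p_prot * sum over synthetic genes of n_x * delta_x * p_x.
#' @param p_prot protease concentration (nM)
#' @param n_x,delta_x,p_x vectors over synthetic genes
#' @export
protease_aggregate <- function(p_prot, n_x, delta_x, p_x) {
  if (length(n_x) == 0) return(0)
  p_prot * sum(n_x * delta_x * p_x)
}

#' Host rate kernel
#'
#' Evaluates the growth rate and physiological rate functions of the
#' coarse-grained cell model:
#' \itemize{
#'  \item eps(t_c) = eps_max * t_c / (t_c + K_eps): translation elongation;
#'  \item lambda(eps, B) = eps * B / ((1 - phi_q) * M): growth rate — the
#'    synthesis flux of the modelled (non-housekeeping) genes over the protein
#'    mass they account for;
#'  \item F_r(t_u, t_c) = t_c / (t_c + tau * t_u): ppGpp-proxy ribosomal
#'    transcription regulation (function of the tRNA charging ratio);
#'  \item psi(t_u, t_c) = psi_max * F_r: tRNA synthesis (co-regulated with
#'    ribosomal genes), entering the balance multiplied by lambda;
#'  \item nu(t_u, sigma) = nu_max * sigma * t_u / (t_u + K_nu): aminoacylation
#'    rate per metabolic protein.
#' }
#'
#' @param state named numeric vector with at least t_c, t_u, R, h
#' @param params host parameters
#' @param mk_sum total m/k demand (native + synthetic)
#' @param delta protease aggregate (see [protease_aggregate])
#' @return list with lambda, eps, F_r, psi, nu, B, D
#' @export
rate_kernel <- function(state, params, mk_sum, delta = 0) {
  if (any(state < 0)) stop("rate_kernel: negative state")
  t_c <- state[["t_c"]]; t_u <- state[["t_u"]]
  R <- state[["R"]]; h <- state[["h"]]
  eps <- params$eps_max * t_c / (t_c + params$K_eps)
  D <- competition_denominator(mk_sum, h, delta, eps, R, params)
  B <- R * mk_sum / D
  lambda <- eps * B / ((1 - params$phi_q) * params$M)
  F_r <- t_c / (t_c + params$tau_ppGpp * t_u)
  if (t_c == 0 && t_u == 0) F_r <- 0
  psi <- params$psi_max * F_r
  nu <- params$nu_max * params$sigma * t_u / (t_u + params$K_nu)
  list(lambda = lambda, eps = eps, F_r = F_r, psi = psi, nu = nu, B = B, D = D)
}

#' Host-cell mass balance right-hand side
#'
#' Derivatives of the six native state variables (mRNAs m_a, m_r; proteins
#' p_a, R; tRNAs t_c, t_u) given precomputed rates. Transcription is
#' proportional to c*alpha*lambda, translation to (eps/n)*(m/k)/D*R, dilution
#' to lambda; charged tRNA is produced at nu*p_a and consumed at eps*B.
#'
#' @param state named numeric vector (m_a, m_r, p_a, R, t_c, t_u)
#' @param params host parameters
#' @param rates rate bundle from [rate_kernel]
#' @return named numeric vector of the six derivatives
#' @export
host_rhs <- function(state, params, rates) {
  lam <- rates$lambda; eps <- rates$eps
  with(as.list(state), {
    c(m_a = params$c_a * params$alpha_a * lam - (params$beta_a + lam) * m_a,
      m_r = rates$F_r * params$c_r * params$alpha_r * lam -
        (params$beta_r + lam) * m_r,
      p_a = eps / params$n_a * (m_a / params$k_a) / rates$D * R - lam * p_a,
      R   = eps / params$n_r * (m_r / params$k_r) / rates$D * R - lam * R,
      t_c = rates$nu * p_a - eps * rates$B - lam * t_c,
      t_u = rates$psi * lam - rates$nu * p_a + eps * rates$B - lam * t_u)
  })
}

#' Native m/k demand of the host
#' @keywords internal
host_mk_sum <- function(state, params) {
  state[["m_a"]] / params$k_a + state[["m_r"]] / params$k_r
}
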