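#' Switch gene transcription regulation
#'
#' Self-activation Hill function of the Punisher switch:
#' F_s = F_sb + (1 - F_sb) * (I*p_s)^eta / ((I*p_s)^eta + K_s^eta).
#' When both K_s and I*p_s are zero the function is defined as F_sb.
#'
#' @param p_s switch protein concentration (nM)
#' @param pp `punisher_params`
#' @return F_s in \[F_sb, 1\]
#' @export
switch_regulation <- function(p_s, pp) {
  if (any(p_s < 0)) stop("switch_regulation: p_s must be >= 0")
  x <- pp$I * p_s
  if (pp$K_s == 0 && all(x == 0)) return(rep(pp$F_sb, length(p_s)))
  hill <- x^pp$eta_s / (x^pp$eta_s + pp$K_s^pp$eta_s)
  pp$F_sb + (1 - pp$F_sb) * hill
}

#' Toggle repression regulation
#'
#' Leaky repression Hill function; the inducer occupancy u of the repressor
#' lowers its effective concentration:
#' F = F_tb + (1 - F_tb) / (1 + ((1-u)*p_rep/K_t)^eta_t).
#' @param p_rep repressor (toggle partner) protein concentration (nM)
#' @param reg regulation descriptor (K_t, eta_t, F_tb)
#' @param u inducer occupancy in \[0,1\]
#' @export
toggle_regulation <- function(p_rep, reg, u = 0) {
  x <- (1 - u) * p_rep / reg$K_t
  reg$F_tb + (1 - reg$F_tb) / (1 + x^reg$eta_t)
}

#' Synthetic gene mass balance
#'
#' mdot = F_x * c_x * alpha_x * lambda - (beta_x + lambda) * m_x
#' pdot = (eps/n_x) * (m_x/k_x)/D * R - (delta_x * p_prot + lambda) * p_x
#'
#' @param gene a `gene_spec`
#' @param m_x,p_x current mRNA and protein concentrations (nM)
#' @param F_x transcription regulation value in \[0,1\]
#' @param rates rate bundle from [rate_kernel]
#' @param R ribosome concentration (nM)
#' @param p_prot protease concentration (nM)
#' @param c_x gene DNA concentration; defaults to the gene's own c_x (overridden
#'   for the dynamically excisable CAT gene)
#' @return c(m = mdot, p = pdot)
#' @export
synthetic_gene_rhs <- function(gene, m_x, p_x, F_x, rates, R, p_prot = 0,
                               c_x = gene$c_x) {
  lam <- rates$lambda
  mdot <- F_x * c_x * gene$alpha_x * lam - (gene$beta_x + lam) * m_x
  pdot <- rates$eps / gene$n_x * (m_x / gene$k_x) / rates$D * R -
    (gene$delta_x * p_prot + lam) * p_x
  c(m = mdot, p = pdot)
}

#' CAT gene excision kinetics
#'
#' Reversible integrase-mediated strand exchange followed by an irreversible
#' conformation change (tetramer binding, Hill exponent fixed at 4):
#' cdot_cat = -k_sx+ * p_i^4/(K_bI^4 + p_i^4) * c_cat + k_sx- * c_LRi
#' cdot_LRi = +forward flux - k_sx- * c_LRi - (k_conf + lambda) * c_LRi
#'
#' @param c_cat,c_LRi pre-/post-strand-exchange DNA concentrations (nM)
#' @param p_i integrase concentration (nM)
#' @param pp `punisher_params`
#' @param lambda growth rate (1/h)
#' @return c(c_cat = ..., c_LRi = ...)
#' @export
excision_rhs <- function(c_cat, c_LRi, p_i, pp, lambda) {
  if (any(c(c_cat, c_LRi, p_i) < 0))
    stop("excision_rhs: inputs must be non-negative")
  fwd <- pp$k_sx_f * p_i^4 / (pp$K_bI^4 + p_i^4) * c_cat
  c(c_cat = -fwd + pp$k_sx_b * c_LRi,
    c_LRi = fwd - pp$k_sx_b * c_LRi - (pp$k_conf + lambda) * c_LRi)
}

#' Intracellular chloramphenicol balance
#'
#' hdot = kappa*(h_ext - h) - h*p_cat/K_C - lambda*h
#' @param h intracellular chloramphenicol (nM)
#' @param p_cat CAT protein concentration (nM)
#' @param kappa membrane diffusion rate (1/h)
#' @param h_ext external chloramphenicol (nM)
#' @param K_C CAT-chloramphenicol affinity constant (nM)
#' @param lambda growth rate (1/h)
#' @export
chloramphenicol_rhs <- function(h, p_cat, kappa, h_ext, K_C, lambda) {
  kappa * (h_ext - h) - h * p_cat / K_C - lambda * h
}
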