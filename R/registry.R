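#' Parameter registry for the resource-aware host cell and Punisher circuit
#'
#' Units used throughout the package: concentrations in nM, time in hours,
#' protein lengths in amino acids (aa). Promoter strengths `alpha` are
#' dimensionless multipliers of the growth rate in the transcription terms.
#'
#' @name registry
NULL

#' Default host-cell parameters
#'
#' Parameters of the coarse-grained resource-aware cell model: two lumped
#' native gene classes (metabolic `a`, ribosomal `r`), tRNA charging and
#' ppGpp-proxy ribosomal regulation, housekeeping proteome fraction and
#' chloramphenicol-ribosome binding. Values are calibrated to yield realistic
#' E. coli physiology on a moderate-quality medium (growth rate ~1.4/h,
#' ribosome concentration ~5e4 nM, translation elongation ~10 aa/s).
#'
#' @param sigma nutrient quality factor (dimensionless, default 0.5)
#' @param h_ext external chloramphenicol concentration (nM)
#' @return a named list of class `host_params`
#' @export
host_params <- function(sigma = 0.5, h_ext = 0) {
  p <- list(
    # native metabolic (a) and ribosomal (r) lumped genes
    c_a = 1, alpha_a = 64700, n_a = 300, beta_a = 6, k_a = 2000,
    c_r = 1, alpha_r = 15250, n_r = 7459, beta_r = 6, k_r = 500,
    # global physiology
    phi_q = 0.59,       # housekeeping proteome mass fraction
    M = 2.9024e9,       # total protein mass (aa per cell volume, nM*aa);
                        # (1-phi_q)*M = 1.19e9 aa is shared by the modelled
                        # metabolic/ribosomal/synthetic genes
    K_D = 1300,         # chloramphenicol-ribosome dissociation constant (nM)
    sigma = sigma,
    h_ext = h_ext,
    kappa = 10,         # chloramphenicol membrane diffusion rate (1/h)
    # rate kernel
    eps_max = 72000,    # max elongation rate (aa/h, = 20 aa/s)
    K_eps = 30000,      # charged-tRNA half-saturation (nM)
    nu_max = 2500,      # max aminoacylation rate per metabolic protein (1/h)
    K_nu = 30000,       # uncharged-tRNA half-saturation (nM)
    psi_max = 120000,   # max tRNA synthesis (nM per unit growth)
    tau_ppGpp = 1       # uncharged:charged tRNA weighting in F_r
  )
  class(p) <- c("host_params", "list")
  validate_host_params(p)
  p
}

validate_host_params <- function(p) {
  num <- vapply(p, is.numeric, logical(1))
  if (!all(num)) stop("host_params fields must be numeric")
  vals <- unlist(p)
  if (any(vals < 0)) stop("host_params fields must be non-negative")
  if (p$phi_q <= 0 || p$phi_q >= 1) stop("phi_q must lie in (0,1)")
  if (p$K_D <= 0) stop("K_D must be positive")
  invisible(p)
}

#' Default initial host state
#'
#' A plausible interior starting point from which the host-only model
#' converges to its positive steady state.
#' @param params host parameters (for consistent h initialisation)
#' @return named numeric vector with elements m_a, m_r, p_a, R, t_c, t_u, h
#' @export
host_init <- function(params = host_params()) {
  c(m_a = 1e4, m_r = 1e3, p_a = 2e6, R = 4e4, t_c = 3e4, t_u = 3e4, h = 0)
}

#' Specification of a synthetic gene
#'
#' @param name gene name (single string)
#' @param c_x gene DNA concentration (nM)
#' @param alpha_x promoter strength (dimensionless)
#' @param n_x protein length (aa)
#' @param beta_x mRNA degradation rate (1/h)
#' @param k_x mRNA-ribosome dissociation constant (nM)
#' @param delta_x protease degradation rate constant (1/(nM h); 0 = not a
#'   protease substrate)
#' @param regulation regulation descriptor: list(type = "constitutive"), or
#'   list(type = "self_activating") (the Punisher switch; parameters come from
#'   `punisher_params`), or list(type = "toggle_repression", partner =
#'   "<gene>", K_t =, eta_t =, F_tb =, pulse_id =)
#' @return object of class `gene_spec`
#' @export
gene_spec <- function(name, c_x, alpha_x, n_x, beta_x = 6, k_x = 2000,
                      delta_x = 0,
                      regulation = list(type = "constitutive")) {
  stopifnot(is.character(name), length(name) == 1)
  vals <- c(c_x, alpha_x, n_x, beta_x, k_x, delta_x)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("gene_spec numeric fields must be finite and non-negative")
  g <- list(name = name, c_x = c_x, alpha_x = alpha_x, n_x = n_x,
            beta_x = beta_x, k_x = k_x, delta_x = delta_x,
            regulation = regulation)
  class(g) <- c("gene_spec", "list")
  g
}

#' Default Punisher circuit parameters
#'
#' Switch/integrase/protease/CAT gene specifications plus the switch
#' self-activation, integrase excision and chloramphenicol parameters.
#' Defaults place the switching threshold between the burden of the packaged
#' single burdensome gene scenario with and without that gene functional.
#'
#' @param I inducer-bound switch protein fraction, in \[0,1\]
#' @param c_si switch/integrase operon DNA concentration (nM); sets both
#'   genes' copy number (they are co-expressed)
#' @return a named list of class `punisher_params`
#' @export
punisher_params <- function(I = 0.87, c_si = 10) {
  pp <- list(
    I = I,
    eta_s = 2,          # switch Hill cooperativity
    K_s = 32000,        # switch-DNA dissociation constant (nM)
    F_sb = 0.01,        # baseline switch promoter activity
    K_bI = 1e4,         # integrase-DNA dissociation constant (nM)
    k_sx_f = 2,         # forward strand exchange rate (1/h)
    k_sx_b = 0.5,       # backward strand exchange rate (1/h)
    k_conf = 10,        # conformation change rate (1/h)
    K_C = 200,          # CAT-chloramphenicol affinity constant (nM)
    genes = list(
      s = gene_spec("s", c_x = c_si, alpha_x = 3000, n_x = 300,
                    beta_x = 6, k_x = 2000, delta_x = 5e-5,
                    regulation = list(type = "self_activating")),
      i = gene_spec("i", c_x = c_si, alpha_x = 3000, n_x = 400,
                    beta_x = 6, k_x = 8000, delta_x = 5e-5,
                    regulation = list(type = "self_activating")),
      prot = gene_spec("prot", c_x = 10, alpha_x = 300, n_x = 300,
                       beta_x = 6, k_x = 2000, delta_x = 0),
      cat = gene_spec("cat", c_x = 10, alpha_x = 400, n_x = 220,
                      beta_x = 6, k_x = 2000, delta_x = 0)
    )
  )
  class(pp) <- c("punisher_params", "list")
  validate_punisher_params(pp)
  pp
}

validate_punisher_params <- function(pp) {
  if (pp$I < 0 || pp$I > 1) stop("I must lie in [0,1]")
  if (pp$F_sb <= 0 || pp$F_sb > 1) stop("F_sb must lie in (0,1]")
  if (pp$eta_s < 1) stop("eta_s must be >= 1")
  rates <- c(pp$K_s, pp$K_bI, pp$k_sx_f, pp$k_sx_b, pp$k_conf, pp$K_C)
  if (any(rates < 0)) stop("punisher rates/constants must be non-negative")
  invisible(pp)
}

#' Default burdensome gene of the single-gene scenario
#' @param c_b DNA concentration (nM)
#' @param alpha_b promoter strength
#' @return a `gene_spec`
#' @export
burdensome_gene <- function(c_b = 10, alpha_b = 5000) {
  gene_spec("b", c_x = c_b, alpha_x = alpha_b, n_x = 300,
            beta_x = 6, k_x = 2000)
}

#' Default toggle switch gene set (two toggles, four genes)
#'
#' Genes t11/t12 form toggle 1 and t21/t22 form toggle 2; each pair mutually
#' represses. Inducer pulses act via `pulse_id` 1..4 lowering the effective
#' repressor concentration.
#' @param alpha_t toggle promoter strength
#' @return named list of four `gene_spec`s
#' @export
toggle_genes <- function(alpha_t = 1800) {
  tg <- function(name, partner, pulse_id)
    gene_spec(name, c_x = 10, alpha_x = alpha_t, n_x = 300, beta_x = 6,
              k_x = 2000,
              regulation = list(type = "toggle_repression", partner = partner,
                                K_t = 50000, eta_t = 2, F_tb = 0.01,
                                pulse_id = pulse_id))
  list(t11 = tg("t11", "t12", 1), t12 = tg("t12", "t11", 2),
       t21 = tg("t21", "t22", 3), t22 = tg("t22", "t21", 4))
}

#' Effective cell volume conversion between nM and molecule counts
#'
#' 1 nM in an E. coli-sized cell (~1 fL) corresponds to ~0.6 molecules.
#' @export
NM_TO_COUNT <- 0.6022
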