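#' Mutant classes of the two-toggle CAT co-expression circuit
#'
#' The 15 non-empty mutant combinations of the four toggle genes collapse,
#' by the exact parameter symmetry between the two toggles (and the
#' convention that t11/t21 are the ON genes), into 9 distinct classes: each
#' toggle independently loses nothing, its ON gene, its OFF gene, or both,
#' and the two toggles are exchangeable.
#' @return named list of representative mutated-gene sets
#' @export
coexpression_mutant_classes <- function() {
  per_toggle <- list(none = character(0), on = "1", off = "2",
                     both = c("1", "2"))
  cls <- list()
  nm <- names(per_toggle)
  for (i in seq_along(per_toggle)) {
    for (j in seq(i, length(per_toggle))) {
      if (i == 1 && j == 1) next   # unmutated
      g1 <- if (length(per_toggle[[i]])) paste0("t1", per_toggle[[i]]) else
        character(0)
      g2 <- if (length(per_toggle[[j]])) paste0("t2", per_toggle[[j]]) else
        character(0)
      genes <- c(g1, g2)
      cls[[paste(nm[i], nm[j], sep = "+")]] <- genes
    }
  }
  cls
}

#' Steady-state growth rate of a CAT co-expression scenario
#'
#' Settles the two-toggle CAT co-expression circuit (both toggles seeded in
#' their designated ON branch where still functional) in
#' chloramphenicol-containing medium.
#' @param k_plus CAT cistron RBS association rate (nM^-1 h^-1)
#' @param mutated mutated toggle genes
#' @param host `host_params`
#' @param k_off_cat downstream-cistron unbinding rate (1/h) in the effective
#'   dissociation constant k = (k_off + eps/n)/k_plus
#' @param horizon steady-state horizon (h)
#' @return steady-state growth rate (1/h)
#' @export
coexpression_growth <- function(k_plus, mutated = character(),
                                host = host_params(h_ext = 5600),
                                k_off_cat = 2e5, horizon = 50) {
  sc <- assemble_scenario("two_toggles_cat_coexpression", host = host,
                          mutated = mutated, k_plus_cat = k_plus,
                          k_off_cat = k_off_cat)
  seed <- c()
  if (!"t11" %in% mutated) seed["p_t11"] <- 3e5
  if (!"t21" %in% mutated) seed["p_t21"] <- 3e5
  ss <- steady_state(sc, init = scenario_init(sc, seed), horizon = horizon)
  ss$rates[["lambda"]]
}

#' Scan the CAT RBS strength for the acceptable co-expression window
#'
#' For each RBS association rate, compares the steady-state growth rate of
#' the unmutated two-toggle co-expression cell against every mutant class
#' (see [coexpression_mutant_classes]). The acceptable window is the
#' sub-range where no mutant out-grows the unmutated cell
#' (max relative growth <= 1). Window boundaries are located by log-linear
#' interpolation of the max-relative-growth curve across 1; a boundary
#' clamped at a scan edge is flagged.
#'
#' @param k_plus scan grid (nM^-1 h^-1); default 20 log-spaced points over
#'   the printed range 0.24 to 60
#' @param host `host_params`
#' @param k_off_cat downstream-cistron unbinding rate (1/h)
#' @param horizon per-point steady-state horizon (h)
#' @return list of class `coexpression_scan`: `table` (k_plus,
#'   lambda_unmutated, one relative-growth column per class,
#'   max_rel_growth, worst_class, acceptable), `window` (lower/upper k_plus
#'   boundary or NA), `window_at_edge` (logical pair)
#' @export
coexpression_scan <- function(k_plus = exp(seq(log(0.24), log(60),
                                               length.out = 20)),
                              host = host_params(h_ext = 5600),
                              k_off_cat = 2e5, horizon = 50) {
  if (any(k_plus <= 0)) stop("k_plus must be positive")
  k_plus <- sort(k_plus)
  cls <- coexpression_mutant_classes()
  rows <- lapply(k_plus, function(kp) {
    lam0 <- coexpression_growth(kp, character(0), host, k_off_cat, horizon)
    rel <- vapply(cls, function(mut)
      coexpression_growth(kp, mut, host, k_off_cat, horizon) / lam0,
      numeric(1))
    c(k_plus = kp, lambda_unmutated = lam0, rel)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  rel_cols <- names(cls)
  tab$max_rel_growth <- apply(tab[rel_cols], 1, max)
  tab$worst_class <- rel_cols[apply(tab[rel_cols], 1, which.max)]
  tab$acceptable <- tab$max_rel_growth <= 1

  # boundaries: crossings of max_rel_growth through 1 (log-linear in k_plus)
  g <- tab$max_rel_growth - 1
  crossings <- c()
  for (i in seq_len(nrow(tab) - 1)) {
    if (sign(g[i]) != sign(g[i + 1]) && g[i] != g[i + 1]) {
      w <- g[i] / (g[i] - g[i + 1])
      crossings <- c(crossings, exp((1 - w) * log(k_plus[i]) +
                                    w * log(k_plus[i + 1])))
    }
  }
  window <- c(NA_real_, NA_real_)
  at_edge <- c(FALSE, FALSE)
  if (any(tab$acceptable)) {
    acc <- range(which(tab$acceptable))
    lo_cross <- crossings[crossings < k_plus[acc[1]]]
    hi_cross <- crossings[crossings > k_plus[acc[2]]]
    if (length(lo_cross)) window[1] <- max(lo_cross) else {
      window[1] <- k_plus[1]; at_edge[1] <- TRUE
    }
    if (length(hi_cross)) window[2] <- min(hi_cross) else {
      window[2] <- k_plus[length(k_plus)]; at_edge[2] <- TRUE
    }
  }
  structure(list(table = tab, window = window, window_at_edge = at_edge,
                 k_off_cat = k_off_cat),
            class = c("coexpression_scan", "list"))
}
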