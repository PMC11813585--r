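# test oracles: independent reconstruction of the translational demand and
# protease load of a punisher scenario state

mk_sum_of <- function(sc, y) {
  hp <- sc$host
  mk <- y[["m_a"]] / hp$k_a + y[["m_r"]] / hp$k_r
  for (g in names(sc$genes)) mk <- mk + y[[paste0("m_", g)]] / sc$genes[[g]]$k_x
  if (!is.null(sc$punisher)) {
    gs <- sc$punisher$genes$s
    gi <- sc$punisher$genes$i
    m_i <- y[["m_s"]] * gi$n_x / gs$n_x
    mk <- mk + y[["m_s"]] / gs$k_x + m_i / gi$k_x +
      y[["m_prot"]] / sc$punisher$genes$prot$k_x +
      y[["m_cat"]] / sc$punisher$genes$cat$k_x
  }
  mk
}

delta_of <- function(sc, y) {
  if (is.null(sc$punisher)) return(0)
  gs <- sc$punisher$genes$s
  gi <- sc$punisher$genes$i
  y[["p_prot"]] * (gs$n_x * gs$delta_x * y[["p_s"]] +
                   gi$n_x * gi$delta_x * y[["p_i"]])
}
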