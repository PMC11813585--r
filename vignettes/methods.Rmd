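---
title: "Methods: the resource-aware cell model, the Punisher, and the population model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the resource-aware cell model, the Punisher, and the population model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the modelling choices behind the `punisher`
package: the single-cell host model, the circuit modules, the
switching-threshold analysis, the hybrid stochastic simulator, and the
48-state population model. Code chunks are illustrative and not evaluated
at build time (several take minutes).

## 1. The coarse-grained host cell

The host is described by six states: metabolic mRNA and protein
(`m_a`, `p_a`), ribosomal mRNA and ribosomes (`m_r`, `R`), and charged and
uncharged tRNA (`t_c`, `t_u`), plus one mRNA/protein pair per synthetic
gene. All concentrations are in nM, time in hours.

Translation is a competition for ribosomes. Every transcript `j`
contributes a demand `m_j / k_j` (`k_j` the effective
ribosome–mRNA dissociation constant), and the competition denominator

```
D = q * (1 + sum_j m_j/k_j - correction(protease load)),   q = (K_D + h)/K_D
```

inflates with intracellular chloramphenicol `h` (which sequesters
ribosomes) and deflates slightly when protease activity removes partially
translated protein. The number of actively translating ribosomes is
`B = R * (sum_j m_j/k_j) / D`, and growth follows the rate kernel

```
lambda = eps(t_c) * B / ((1 - phi_q) * M)
```

with `eps` Michaelis–Menten in charged tRNA, `M` the total cellular
protein mass in amino acids, and `phi_q` the housekeeping mass fraction.
tRNA charging `nu` saturates in uncharged tRNA and scales with nutrient
quality `sigma`; ribosomal transcription is regulated by the
charged:uncharged ratio (a ppGpp proxy), `F_r = t_c / (t_c + tau * t_u)`.

Parameter values live in a single registry (`host_params()`,
`punisher_params()`, `toggle_genes()`) calibrated once to standard
E. coli physiology (`lambda` about 1.4/h, 5e4 nM ribosomes in rich
medium); they are the package's defaults and are never tuned per
experiment.

```{r}
library(punisher)
ss <- steady_state(assemble_scenario("host_only"))
ss$rates[["lambda"]]
```

## 2. Circuit modules

Circuits are assembled by topology name with `assemble_scenario()`:

* **Burdensome gene** — one constitutive mRNA/protein pair; its demand
  `m_b/k_b` depresses `lambda` through `D`.
* **Toggle switches** — two mutually repressing leaky-Hill gene pairs,
  flippable by rectangular inducer pulses.
* **The Punisher** — a self-activating switch (`F_s`, leaky Hill with
  inducer-modulated binding) translated from the same transcript as an
  integrase (`m_i = m_s * n_i / n_s`), both destabilised by a
  co-expressed protease; the integrase excises the CAT
  (chloramphenicol-resistance) DNA through a reversible strand-exchange
  step committed by an irreversible conformation change. In
  chloramphenicol medium, excision is lethal punishment.
* **CAT co-expression** — the CAT cistron rides on each toggle transcript
  so that losing a toggle gene also costs resistance; the scanned design
  parameter is the CAT ribosome association rate `k+`.

The mutation of any gene is modelled by zeroing its DNA concentration
(`mutated =` argument or timed `events`).

## 3. Switching-threshold analysis

At steady state, the switch's self-activation balance reduces to one
dimension. For a candidate switch level `p_s`, the regulation value the
cell must supply is

```
F_s_req(p_s, Xi) = p_s (1+chi) * Xi / (xi_s_max + xi_i_max) / (cap - p_s (1+chi))
```

which is linear in the total burden `Xi` (the summed demand of every
other gene, `burden_summary()`), with `chi` the protease-degradation to
dilution ratio. Intersections with the actual promoter response
`switch_regulation(p_s)` are the fixed points (`find_fixed_points()`;
dense log-grid sign scan refined by bisection, graphical stability
criterion). The low-expression equilibrium exists only above a
saddle-node burden `Xi_hat` (`find_threshold()`): while the burdensome
gene is intact (`Xi > Xi_hat`) the Punisher idles low; when a mutation
drops the burden below `Xi_hat`, only the high branch remains and the
integrase fires. `fold_change_bound()` converts the two fixed points into
a lower bound on the excision-propensity fold change, and
`design_space_scan()` maps the acceptable design region.

```{r}
host <- host_params(h_ext = 5600)
sc <- assemble_scenario("single_burdensome_gene_with_punisher", host = host)
bs <- burden_summary(sc)
find_threshold(punisher_params(), bs, host)
```

## 4. Hybrid stochastic simulation and rate estimation

Switch activation in a low-copy circuit is a rare, noise-driven event, so
the Punisher species are simulated discretely while the host stays
deterministic (`simulate_hybrid()`):

* fixed leap `tau = 0.01 h`, halved and retried if any continuous state
  would go negative;
* discrete species (`m_s`, `p_s`, `p_i`, and the two DNA states) in
  molecule counts (0.6022 molecules per nM in an E. coli volume); births
  are Poisson, removals are binomial thinning with probability
  `1 - exp(-rate*tau)`, so counts cannot go negative; DNA strand exchange
  is per-copy binomial with back-exchange and conformation commitment as
  competing thinned outcomes;
* fast variables are eliminated by quasi-steady-state: the charged/uncharged
  tRNA partition is re-solved by bisection each leap (total tRNA is the
  slow variable), and intracellular chloramphenicol is set to its
  quasi-steady level given CAT and the previous leap's growth rate.

`estimate_transition_rates()` runs an ensemble from a background's
low state and converts first crossings of that background's basin
boundary (its unstable fixed point, with a ±10% hysteresis band) into an
exponential rate with exact gamma confidence intervals
(`rate_estimate()`); ensembles with zero events report rate 0 with a
one-sided upper bound and a flag. The estimator is validated against an
exactly simulated telegraph process (`simulate_telegraph()`).

## 5. The 48-state population model

A cell is classified by which of four mutable units are functional —
B (burdensome gene), S (switch+integrase, one unit), P (protease),
C (CAT DNA) — and by its Punisher expression state (0/L/H):
16 genetic states × 3 = 48 (`enumerate_states()`, labels like
`"B′SPC:H"`). For each state, the single-cell model is settled (with
excision frozen, since excision is a population-level transition) to get
its division rate, product content and integrase level
(`single_cell_library()`); states whose intended equilibrium does not
exist inherit a progenitor's properties (units restored in order B, S,
P, C), except that product content is always zero for B-mutated cells.

The turbidostat balance is `xdot = (D + A + T) x - L(x) x` with

* `D = 2 d P - diag(d)`: division with independent per-unit mutation
  probability `mu`; columns sum to `d_j` for any `mu`;
* `A`: CAT excision at each state's effective rate
  `k_sx+ * Hill4(p_i) * k_conf / (k_sx- + k_conf + lambda)`;
* `T`: Punisher L→H/H→L/L→0/H→0 rates from `transition_rate_table()`
  (stochastic first-passage for S-functional states, deterministic
  protein decay for S-mutated ones);
* `L(x) = sum(x d) / sum(x)`: turbidostat dilution, keeping `sum(x)`
  constant.

Productivity is summarised by `Theta(t)` (population-average per-cell
production rate), its integral `Y`, and the function duration `tau`
(time above half-maximal `Theta`); `sweep_mu()` compares the Punisher
population against a no-Punisher control across mutation rates.

```{r}
model <- population_model(mu = 1e-12)
traj <- simulate_population(model, population_init(model, "punisher"))
productivity_metrics(traj, model)$tau
```

## 6. Configs, fixtures and the CLI

Experiments are described by a validated YAML schema
(`scenario_config()`, `load_config()`; unknown keys and parameter symbols
are rejected by name). Six packaged fixtures (`make_fixture()`,
`run_fixture()`) reproduce the package's headline experiments with
built-in qualitative checks. A thin command-line wrapper ships at
`inst/exec/punisher-sim` (`run`, `scan`, `population`), writing CSV
tables plus a JSON summary and manifest.
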