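Package: punisher
Title: Resource-Aware Design of the Punisher Burden-Sensing Genetic Stability Circuit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-guided design toolkit for the Punisher, a burden-sensing
    genetic stability circuit. Implements a coarse-grained resource-aware
    single-cell ODE model of an E. coli host with pluggable synthetic
    circuits (constitutive burdensome genes, toggle switches, essential-gene
    co-expression, and the Punisher's protease-destabilised self-activating
    switch coupled to an integrase that irreversibly excises a
    chloramphenicol resistance gene), an analytical switching-threshold
    toolkit based on steady-state burden reduction and saddle-node
    bifurcation detection, a hybrid tau-leaping stochastic simulator for
    estimating circuit state-transition rates, and a 48-state turbidostat
    population model linking circuit design parameters to the genetic
    stability and productivity of engineered cell populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
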