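# synthetic library: correct state bookkeeping with made-up cell properties,
# so matrix structure can be tested without any ODE/stochastic work
fake_lib <- function() {
  st <- enumerate_states()
  set.seed(42)
  st$lambda <- runif(48, 0.3, 1.8)
  st$p_b <- ifelse(st$B, runif(48, 1e4, 1e5), 0)
  st$p_i <- ifelse(st$punisher == "H" & st$S, 5e4,
                   ifelse(st$punisher == "L" & st$S, 10, 0))
  st$decay_rate <- st$lambda + 1
  st
}
empty_rates <- data.frame(genetic_state = character(0), from = character(0),
                          to = character(0), rate = numeric(0))

test_that("state enumeration: 48 states, 16 genetic backgrounds, canonical order", {
  st <- enumerate_states()
  expect_equal(nrow(st), 48)
  expect_equal(st$index, 0:47)
  expect_equal(nrow(unique(st[, c("B", "S", "P", "C")])), 16)
  expect_equal(anyDuplicated(st$label), 0)
  expect_equal(st$label[1], state_label(FALSE, FALSE, FALSE, FALSE, "0"))
  expect_equal(st$label[48], "BSPC:H")
  expect_equal(state_label(FALSE, TRUE, TRUE, TRUE, "H"),
               paste0("B\u2032SPC:H"))
})

test_that("state labels round-trip through the parser", {
  st <- enumerate_states()
  for (r in seq_len(nrow(st))) {
    p <- parse_state_label(st$label[r])
    expect_equal(p$index, st$index[r])
    expect_equal(c(p$B, p$S, p$P, p$C),
                 c(st$B[r], st$S[r], st$P[r], st$C[r]))
    expect_equal(p$punisher, st$punisher[r])
  }
  # ASCII apostrophe accepted in place of the prime
  expect_equal(parse_state_label("B'SPC:H")$index,
               parse_state_label("B\u2032SPC:H")$index)
  expect_error(parse_state_label("BSPC"), "malformed")
  expect_error(parse_state_label("XSPC:L"), "malformed")
  expect_error(parse_state_label("BSPC:Q"), "malformed")
})

test_that("division matrix columns sum to the division rate for any mu", {
  lib <- fake_lib()
  for (mu in c(0, 1e-12, 1e-3, 0.2, 1)) {
    m <- build_matrices(lib, empty_rates, mu = mu)
    expect_equal(colSums(m$D), unname(lib$lambda), tolerance = 1e-12)
    expect_true(all(m$D - diag(diag(m$D)) >= 0))
  }
  expect_error(build_matrices(lib, empty_rates, mu = -0.1), "mu")
})

test_that("mu = 0 division is pure growth; single-mutant entries are analytic", {
  lib <- fake_lib()
  m0 <- build_matrices(lib, empty_rates, mu = 0)
  expect_equal(m0$D, diag(lib$lambda))
  mu <- 0.01
  m <- build_matrices(lib, empty_rates, mu = mu)
  j <- which(lib$label == "BSPC:L")
  i <- which(lib$label == "B\u2032SPC:L")
  expect_equal(m$D[i, j], 2 * lib$lambda[j] * mu * (1 - mu)^3)
  expect_equal(m$D[j, j], 2 * lib$lambda[j] * (1 - mu)^4 - lib$lambda[j])
  # mutation never restores a unit: no flow from a mutated to a functional state
  expect_equal(m$D[j, i], 0)
})

test_that("excision and punisher-transition matrices conserve cells", {
  lib <- fake_lib()
  rates <- data.frame(genetic_state = "BSPC", from = "L", to = "H",
                      rate = 0.5, stringsAsFactors = FALSE)
  m <- build_matrices(lib, rates, mu = 1e-12)
  expect_equal(colSums(m$A), rep(0, 48), tolerance = 1e-12)
  expect_equal(colSums(m$T), rep(0, 48), tolerance = 1e-12)
  # A only removes CAT: source columns all have C functional, and the flow
  # lands on the same genetic background and punisher state with C excised
  for (j in which(abs(diag(m$A)) > 0)) {
    expect_true(lib$C[j])
    i <- setdiff(which(m$A[, j] > 0), j)
    expect_equal(unname(unlist(lib[i, c("B", "S", "P")])),
                 unname(unlist(lib[j, c("B", "S", "P")])))
    expect_false(lib$C[i])
    expect_equal(lib$punisher[i], lib$punisher[j])
  }
  jL <- which(lib$label == "BSPC:L"); jH <- which(lib$label == "BSPC:H")
  expect_equal(m$T[jH, jL], 0.5)
  expect_equal(m$T[jL, jL], -0.5)
  expect_error(build_matrices(lib, transform(rates, rate = -1)), "negative")
})

test_that("turbidostat dilution keeps total cell count constant", {
  expect_equal(dilution(c(1, 1), c(0.5, 1.5)), 1)
  expect_equal(dilution(c(2, 0), c(0.5, 1.5)), 0.5)
  expect_error(dilution(c(0, 0), c(1, 1)), "empty")
  lib <- fake_lib()
  lib$lambda <- rep(0.9, 48)   # uniform growth: x must stay constant
  lib$p_i <- 0                 # no integrase: excision matrix is zero
  model <- build_matrices(lib, empty_rates, mu = 0)
  model$t_cult <- 10
  class(model) <- c("population_model", "list")
  x0 <- setNames(numeric(48), model$states)
  x0[c(1, 20, 48)] <- c(3e8, 2e8, 5e8)
  traj <- simulate_population(model, x0, t_cult = 10, dt = 1)
  X <- as.matrix(traj[, model$states])
  expect_equal(unname(rowSums(X)), rep(1e9, nrow(X)), tolerance = 1e-6)
  expect_equal(unname(X[nrow(X), ]), unname(x0), tolerance = 1e-6)
})

test_that("productivity metrics: constant and collapsing Theta", {
  model <- list(d = 1, p_b = 1)
  traj <- data.frame(time = 0:100, Theta = rep(2, 101))
  pm <- productivity_metrics(traj, model)
  expect_equal(pm$Y, 200)     # integral of constant 2 over 100 h
  expect_equal(pm$tau, 100)   # never drops below half-max
  traj2 <- data.frame(time = 0:100, Theta = c(rep(2, 41), rep(0, 60)))
  pm2 <- productivity_metrics(traj2, model)
  expect_equal(pm2$tau, 40.5) # half-weight on the crossing interval
  traj3 <- data.frame(time = 0:10, Theta = rep(0, 11))
  expect_equal(productivity_metrics(traj3, model)$Y, 0)
})

test_that("real single-cell library is total and anchored correctly", {
  lib <- single_cell_library()
  expect_equal(nrow(lib), 48)
  expect_true(all(is.finite(lib$lambda)) && all(lib$lambda > 0))
  expect_true(all(lib$p_b >= 0))
  # cells without the burdensome gene make no product
  expect_true(all(lib$p_b[!lib$B] == 0))
  # the engineered start state exists as a genuine low equilibrium
  expect_true(lib$exists[lib$label == "BSPC:L"])
  # losing the burdensome gene without punishment grows faster than BSPC:L
  expect_gt(lib$lambda[lib$label == "B\u2032SPC:0"],
            lib$lambda[lib$label == "BSPC:L"])
  # punished cells grow slower than their unpunished counterparts
  expect_lt(lib$lambda[lib$label == "B\u2032SPC\u2032:H"],
            lib$lambda[lib$label == "B\u2032SPC\u2032:L"])
  props <- resolve_cell_properties("B\u2032SPC:H", lib)
  expect_true(is.finite(props$d) && props$d > 0)
  expect_gt(props$excision_rate, 0)
})
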