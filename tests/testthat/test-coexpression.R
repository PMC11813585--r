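test_that("mutant classes: 9 toggle-symmetric classes of gene losses", {
  cls <- coexpression_mutant_classes()
  expect_equal(length(cls), 9)
  expect_equal(anyDuplicated(names(cls)), 0)
  genes <- c("t11", "t12", "t21", "t22")
  for (m in cls) {
    expect_gt(length(m), 0)          # every class is a genuine mutant
    expect_true(all(m %in% genes))
    expect_equal(anyDuplicated(m), 0)
  }
  # the classes are exactly the unordered pairs of per-toggle loss patterns
  # {none, on, off, both} minus the fully functional none+none
  pattern <- function(m, k) {
    on <- paste0("t", k, "1") %in% m
    off <- paste0("t", k, "2") %in% m
    if (on && off) "both" else if (on) "on" else if (off) "off" else "none"
  }
  pats <- c("none", "on", "off", "both")  # severity order used in names
  canon <- vapply(cls, function(m) {
    p <- c(pattern(m, 1), pattern(m, 2))
    paste(p[order(match(p, pats))], collapse = "+")
  }, character(1))
  expect_setequal(unname(canon), names(cls))
  all_pairs <- unique(apply(expand.grid(pats, pats), 1, function(p)
    paste(p[order(match(p, pats))], collapse = "+")))
  expect_setequal(names(cls), setdiff(all_pairs, "none+none"))
})

test_that("co-expression growth responds to CAT binding strength", {
  # a functional cell protected by strongly bound CAT grows faster than one
  # whose CAT mRNA barely recruits ribosomes, in drugged medium
  g_strong <- coexpression_growth(k_plus = 60, mutated = character(0))
  g_weak <- coexpression_growth(k_plus = 0.24, mutated = character(0))
  expect_gt(g_strong, g_weak)
  expect_gt(g_weak, 0)
})
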