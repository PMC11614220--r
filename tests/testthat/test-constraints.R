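test_that("the default constraint set encodes the measurement categories", {
  cnet <- stroma_compressed()$network
  cs <- stroma_cs()
  # hard activity: glucose uptake, lactate secretion, glutamine uptake,
  # plus the demanded biomass production
  expect_equal(nrow(cs$hard_active), 4L)
  expect_true(all(c("EX_GLUC", "EX_GLN") %in% cs$hard_active$rxn))
  # lactate and biomass exchanges are merged into subsets when compressed
  expect_true(any(grepl("EX_LAC", cs$hard_active$rxn)))
  expect_true(any(grepl("EX_BM", cs$hard_active$rxn)))
  # aspartate is uptake-only: its secretion direction is forbidden
  asp <- uptake_direction(cnet, "ASPx")
  expect_true(any(cs$forbidden_direction$rxn == asp$rxn &
                    cs$forbidden_direction$dir == asp$secretion))
  # alanine is secretion-only: its uptake direction is forbidden
  ala <- uptake_direction(cnet, "ALAx")
  expect_true(any(cs$forbidden_direction$rxn == ala$rxn &
                    cs$forbidden_direction$dir == ala$uptake))
  # glycine is bidirectional: no constraint on its exchange
  gly <- uptake_direction(cnet, "GLYx")
  expect_false(gly$rxn %in% cs$forbidden_direction$rxn)
  expect_false(gly$rxn %in% cs$hard_active$rxn)
  expect_equal(cs$max_support, 60L)
  expect_equal(nrow(cs$linear), 2L)
  # a direction cannot be both required and forbidden
  expect_error(constraint_set(hard_active = directed("R", "fwd"),
                              forbidden_direction = directed("R", "fwd")),
               "both required and forbidden")
})

test_that("satisfies() reports labelled violations", {
  cs <- constraint_set(
    hard_active = directed(c("A", "B"), "fwd"),
    forbidden_direction = directed("C", "bwd"),
    linear = data.frame(greater = "D", lesser = "E"),
    max_support = 3L
  )
  ok <- satisfies(c(A = 1, B = 0.5, D = 1, E = 0.2), cs)
  expect_false(ok$ok)            # support 4 >= cap 3
  expect_equal(ok$violations, "size")
  miss <- satisfies(c(A = 1, D = 1), cs, eps = 1e-6)
  expect_true("hard:B" %in% miss$violations)
  back <- satisfies(c(A = 1, B = 1, C = -0.5, D = 1), cs)
  expect_true("forbidden:C" %in% back$violations)
  tie <- satisfies(c(A = 1, B = 1, D = 0.5, E = 0.5), cs, eps = 1e-6)
  expect_true("linear:D>E" %in% tie$violations)
  # equality of collagen and biomass production violates the strict rule
  lin2 <- constraint_set(linear = data.frame(greater = "D", lesser = "E"))
  expect_false(satisfies(c(D = 1, E = 1), lin2)$ok)
  expect_true(satisfies(c(D = 1, E = 0.5), lin2)$ok)
})

test_that("the sampler equals the constraint-filtered oracle on toy networks", {
  toy <- branched_toy()
  bf <- brute_force_efms(toy)
  cs <- constraint_set(hard_active = directed("EX_P", "fwd"))
  manual <- Filter(function(m) satisfies(m, cs)$ok, bf)
  got <- sample_constrained_efms(toy, cs, n = 10, seed = 1)
  keys <- function(ms) sort(vapply(ms, function(m)
    paste(m$support, collapse = ";"), ""))
  expect_equal(keys(got), keys(manual))

  for (seed in c(3, 9)) {
    rnd <- generate_toy_network("random", 12, seed = seed)
    first_ex <- exchange_reactions(rnd)[1]
    cs2 <- constraint_set(hard_active = directed(first_ex, "fwd"),
                          max_support = 8L)
    manual2 <- Filter(function(m) satisfies(m, cs2)$ok, brute_force_efms(rnd))
    got2 <- sample_constrained_efms(rnd, cs2, n = 50, seed = seed)
    expect_equal(keys(got2), keys(manual2), label = paste("seed", seed))
  }
})

test_that("the LP sampling path is sound and complete on small networks", {
  toy <- branched_toy()
  cs <- constraint_set(hard_active = directed("EX_P", "fwd"))
  manual <- Filter(function(m) satisfies(m, cs)$ok, brute_force_efms(toy))
  # force the randomized path by disabling the enumeration shortcut
  got <- sample_constrained_efms(toy, cs, n = 10, seed = 4, enum_max_cols = 0L,
                                 stall_rounds = 40L)
  keys <- function(ms) sort(vapply(ms, function(m)
    paste(m$support, collapse = ";"), ""))
  expect_equal(keys(got), keys(manual))
  for (m in got) {
    expect_true(m$verified_elementary)
    expect_true(is_steady_state(m, toy))
    expect_true(satisfies(m, cs)$ok)
  }
})

test_that("an unsatisfiable demand returns an empty, flagged result", {
  toy <- generate_toy_network("chain", 4)
  # demand secretion through a reaction the chain cannot reverse
  cs <- constraint_set(hard_active = directed("EX_in", "bwd"))
  got <- sample_constrained_efms(toy, cs, n = 5, seed = 1)
  expect_length(got, 0L)
  expect_true(isTRUE(attr(got, "infeasible")))
})

test_that("sampling on the packaged model is sound and deterministic", {
  cnet <- stroma_compressed()$network
  cs <- stroma_cs()
  modes <- stroma_modes()
  expect_gt(length(modes), 5L)
  for (m in modes) {
    expect_true(m$verified_elementary)
    expect_true(is_steady_state(m, cnet, tol = 1e-8))
    expect_true(satisfies(m, cs, eps = 1e-6)$ok)
    expect_lt(length(m$support), 60L)
  }
  # phenotype guaranteed by the constraints: Warburg effect, glutamine
  # uptake, growth, collagen and stroma production in every mode
  al <- default_exchange_aliases()
  for (m in modes) {
    expect_lt(exchange_flux(m, "glucose", cnet, al), 0)
    expect_gt(exchange_flux(m, "lactate", cnet, al), 0)
    expect_lt(exchange_flux(m, "glutamine", cnet, al), 0)
    expect_gt(exchange_flux(m, "biomass", cnet, al), 0)
    expect_gt(exchange_flux(m, "collagen", cnet, al), 0)
    expect_gt(exchange_flux(m, "stroma", cnet, al), 0)
  }
  rerun <- sample_constrained_efms(cnet, cs, n = 10L, seed = 101L,
                                   stall_rounds = 150L, time_limit = 120)
  first10 <- stroma_modes()[seq_len(min(10L, length(stroma_modes())))]
  expect_equal(support_keys(rerun), support_keys(first10))
})

test_that("constraint sets round-trip through the JSON config", {
  cs <- stroma_cs()
  path <- withr::local_tempfile(fileext = ".json")
  write_constraint_set(cs, path)
  back <- read_constraint_set(path)
  expect_equal(back$hard_active, cs$hard_active)
  expect_equal(back$forbidden_direction, cs$forbidden_direction)
  expect_equal(back$max_support, cs$max_support)
  expect_equal(back$linear$greater, cs$linear$greater)
})
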