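mode_signature <- function(ms) sort(vapply(ms, function(m) {
  v <- normalize_flux(if (inherits(m, "flux_mode")) m$v else m)
  nz <- which(abs(v) > 1e-9)
  if (v[nz[1L]] < 0) v <- -v
  paste(names(v)[nz], sign(v[nz]), collapse = ";")
}, ""))

test_that("steady-state and elementarity tests behave on hand-built fluxes", {
  chain <- generate_toy_network("chain", 4)
  full <- c(EX_in = 1, R1 = 1, R2 = 1, EX_out = 1)
  half <- c(EX_in = 1, R1 = 1)
  expect_true(is_steady_state(stats::setNames(numeric(4),
                                              names(full)), chain))
  expect_true(is_steady_state(full, chain))
  expect_false(is_steady_state(half, chain))
  expect_true(is_elementary(full, chain))
  expect_false(is_elementary(stats::setNames(numeric(4), names(full)), chain))
})

test_that("a superposition of distinct EFMs fails the rank test", {
  diam <- generate_toy_network("diamond")
  efms <- brute_force_efms(diam)
  expect_length(efms, 2L)
  both <- efms[[1]]$v + efms[[2]]$v
  expect_true(is_steady_state(both, diam))
  expect_false(is_elementary(both, diam))
  # any flux whose support strictly contains an EFM support is non-elementary
  for (m in efms) expect_true(is_elementary(m, diam))
})

test_that("enumeration handles the canonical toy families", {
  expect_length(enumerate_efms_exhaustive(generate_toy_network("chain", 4)), 1L)
  expect_length(enumerate_efms_exhaustive(generate_toy_network("diamond")), 2L)
  # cycle: through-flux plus the internal loop
  cyc <- enumerate_efms_exhaustive(generate_toy_network("cycle", 3))
  expect_length(cyc, 2L)
  sizes <- sort(vapply(cyc, function(m) length(m$support), 0L))
  expect_equal(sizes, c(2L, 3L))
})

test_that("no enumerated mode activates both halves of a split pair", {
  mets <- rbind(metabolite(c("Sx", "Px"), compartment = "external",
                           boundary = TRUE),
                metabolite(c("A", "B")))
  net <- metabolic_network(mets, list(
    reaction("EX_in", c(Sx = -1, A = 1)),
    reaction("MID", c(A = -1, B = 1), reversible = TRUE),
    reaction("EX_out", c(B = -1, Px = 1))
  ))
  modes <- enumerate_efms_exhaustive(net)
  expect_length(modes, 1L)
  expect_equal(sort(modes[[1]]$support), c("EX_in", "EX_out", "MID"))
})

test_that("double description matches brute force on seeded random networks", {
  for (seed in 1:8) {
    toy <- generate_toy_network("random", 12, seed = seed)
    dd <- enumerate_efms_exhaustive(toy)
    bf <- brute_force_efms(toy)
    expect_equal(mode_signature(dd), mode_signature(bf),
                 label = paste("seed", seed))
    for (m in dd) {
      expect_true(is_steady_state(m, toy))
      expect_true(m$verified_elementary)
      # conical invariance: positive rescaling preserves both properties
      expect_true(is_steady_state(3.7 * m$v, toy))
      expect_true(is_elementary(3.7 * m$v, toy))
    }
  }
})

test_that("infeasible networks yield no modes and guards refuse big inputs", {
  # input with no outlet
  mets <- rbind(metabolite("Sx", compartment = "external", boundary = TRUE),
                metabolite("A"))
  dead <- metabolic_network(mets, list(reaction("EX_in", c(Sx = -1, A = 1))))
  expect_length(brute_force_efms(dead), 0L)
  expect_length(enumerate_efms_exhaustive(dead), 0L)
  expect_error(enumerate_efms_exhaustive(stroma_net(), max_cols = 32),
               "use sample_constrained_efms")
  expect_error(brute_force_efms(stroma_net()), "guard")
})

test_that("EFM matrices round-trip through the CSV layout", {
  toy <- generate_toy_network("diamond")
  modes <- enumerate_efms_exhaustive(toy)
  path <- withr::local_tempfile(fileext = ".csv")
  write_efm_csv(modes, path)
  back <- read_efm_csv(path, toy)
  expect_equal(mode_signature(back), mode_signature(modes))
  # values renormalized to unit max on load
  expect_true(all(vapply(back, function(m) max(abs(m$v)), 0) == 1))
  expect_error(read_efm_csv(path, generate_toy_network("chain", 4)),
               "unknown reaction column")
})
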