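test_that("network construction validates ids, compartments and stoichiometry", {
  mets <- rbind(metabolite("Ax", compartment = "external", boundary = TRUE),
                metabolite("A"))
  net <- metabolic_network(mets, list(reaction("EX_A", c(Ax = -1, A = 1))))
  expect_s3_class(net, "metabolic_network")
  expect_equal(exchange_reactions(net), "EX_A")

  expect_error(metabolic_network(rbind(mets, metabolite("A")), list()),
               "duplicate metabolite")
  expect_error(metabolic_network(metabolite("B", compartment = "nucleus"),
                                 list()), "unknown compartment")
  expect_error(reaction("R0", c(A = 0)), "no nonzero coefficient")
  expect_error(reaction("R1", c(A = 1), reversible = FALSE, lb = -5),
               "lb >= 0")
  expect_error(
    metabolic_network(mets, list(reaction("R2", c(Zz = 1)))),
    "unknown metabolite")
})

test_that("the stoichiometric matrix covers internal metabolites in order", {
  net <- stroma_net()
  N <- stoich_matrix(net)
  expect_equal(rownames(N), net$metabolites$id[!net$metabolites$boundary])
  expect_equal(colnames(N), vapply(net$reactions, `[[`, "", "id"))
  # spot value: collagen condensation consumes 100 bricks
  expect_equal(N["CBrick", "COLLAG"], -100)
})

test_that("protein synthesis reactions follow the inverse-length rule", {
  comp <- protein_compositions()
  for (nm in names(comp)) {
    r <- protein_synthesis_reaction(nm, comp[[nm]]$counts, comp[[nm]]$length)
    reactants <- r$stoich[r$stoich < 0]
    expect_equal(sum(-reactants), 1, tolerance = 1e-9)
    expect_equal(r$stoich[[nm]] * comp[[nm]]$length, 1, tolerance = 1e-9)
    expect_false(r$reversible)
  }
  # identity case: single-residue protein
  tiny <- protein_synthesis_reaction("VEGFA", c(MET = 1), 1)
  expect_equal(unname(tiny$stoich[c("MET", "VEGFA")]), c(-1, 1))
  # validation
  expect_error(protein_synthesis_reaction("X", c(MET = 3), 4), "sum to 3")
  expect_error(protein_synthesis_reaction("X", c(FOO = 2), 2),
               "unknown amino-acid pool")
})

test_that("marker protein coefficients match the published reactions", {
  # printed stoichiometries, rounded as published
  printed <- list(
    IL1B = c(MET = 0.045, ALAc = 0.048, GLUTc = 0.078, TIV = 0.13,
             PROc = 0.056, YFLKW = 0.275, SERc = 0.078, GLYc = 0.048,
             ASNc = 0.045, ASPc = 0.074, GLNc = 0.067, CYSc = 0.019,
             ARGc = 0.022, HISc = 0.015),
    TNFA = c(MET = 0.009, SERc = 0.086, TIV = 0.163, GLUTc = 0.069,
             ARGc = 0.06, ASPc = 0.03, YFLKW = 0.245, ALAc = 0.082,
             PROc = 0.064, GLYc = 0.073, GLNc = 0.056, CYSc = 0.017,
             HISc = 0.017, ASNc = 0.03),
    VEGFA = c(MET = 0.034, ASNc = 0.03, YFLKW = 0.237, SERc = 0.065,
              TIV = 0.108, HISc = 0.047, ALAc = 0.034, GLNc = 0.056,
              PROc = 0.065, GLUTc = 0.069, GLYc = 0.06, ASPc = 0.034,
              ARGc = 0.082, CYSc = 0.078)
  )
  products <- c(IL1B = 0.00371, TNFA = 0.00429, VEGFA = 0.00431)
  net <- stroma_net()
  for (nm in names(printed)) {
    r <- net$reactions[[match(nm, vapply(net$reactions, `[[`, "", "id"))]]
    for (pool in names(printed[[nm]])) {
      expect_lt(abs(-r$stoich[[pool]] - printed[[nm]][[pool]]), 5e-4,
                label = paste(nm, pool))
    }
    expect_lt(abs(r$stoich[[nm]] - products[[nm]]), 1e-5)
  }
})

test_that("the stroma extension reproduces the published block stoichiometry", {
  net <- stroma_net()
  rx <- function(id) net$reactions[[match(id, vapply(net$reactions, `[[`, "", "id"))]]
  expect_equal(rx("CBS")$stoich[c("GLYc", "XYAA", "PROc", "HYPc", "CBrick")],
               c(GLYc = -0.33, XYAA = -0.50, PROc = -0.085, HYPc = -0.085,
                 CBrick = 1))
  expect_equal(rx("COLLAG")$stoich, c(CBrick = -100, Collagen = 1))
  xy <- rx("XYAAS")$stoich
  expect_equal(xy[["XYAA"]], 14)
  expect_equal(unname(xy[c("ALAc", "ARGc", "SERc", "TIV", "YFLKW", "GLNc",
                           "ASPc", "GLUTc")]), rep(-1, 8))
  expect_equal(rx("STROMA")$stoich,
               c(Inflam = -1, GrowthFactor = -1, Stroma = 1))
  expect_equal(rx("FACT")$stoich, c(VEGFA = -1, GrowthFactor = 1))
  expect_equal(rx("INF1")$stoich, c(IL1B = -1, Inflam = 1))
  expect_equal(rx("INF2")$stoich, c(TNFA = -1, Inflam = 1))
  # a missing required pool is reported by name
  broken <- synthetic_core_model()
  broken$metabolites <- broken$metabolites[broken$metabolites$id != "CYSc", ]
  broken$reactions <- Filter(function(r) !"CYSc" %in% names(r$stoich),
                             broken$reactions)
  expect_error(build_stroma_extension(broken), "CYSc")
})

test_that("stroma flux needs an inflammation marker and the growth factor", {
  # with VEGFA knocked out no steady-state flux can reach the stroma
  # exchange even though IL1B alone can still produce Inflam
  net <- stroma_net()
  cs <- constraint_set(hard_active = directed("STROMA", "fwd"))
  expect_true(is_essential(net, cs, "VEGFA"))
  expect_true(is_essential(net, cs, "FACT"))
  # INF1 alone is not essential: INF2 via TNFA substitutes
  expect_false(is_essential(net, cs, "INF1"))
})

test_that("exchange fluxes are uptake-negative regardless of orientation", {
  net <- stroma_net()
  v <- c(EX_GLUC = 2, EX_LAC = 3)
  expect_equal(exchange_flux(v, "GLUCc", net), -2)  # written Xx -> Xc
  expect_equal(exchange_flux(v, "LACc", net), 3)    # written Xc -> Xx
  al <- default_exchange_aliases()
  expect_equal(exchange_flux(v, "glucose", net, al), -2)
  expect_equal(exchange_flux(v, "lactate", net, al), 3)
  # boundary-species lookup agrees with internal lookup
  expect_equal(exchange_flux(v, "GLUCx", net), exchange_flux(v, "GLUCc", net))
  expect_error(exchange_flux(v, "ATPc", net), "no exchange reaction")
  # and works on the compressed network where EX_LAC is merged with LDH
  cm <- stroma_compressed()
  vc <- c("EX_LAC__LDH" = 1.5)
  expect_equal(exchange_flux(vc, "LACx", cm$network), 1.5)
})
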