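#' Synthetic core model of central cancer-cell metabolism
#'
#' A self-contained, synthetic reconstruction of a three-compartment core
#' carbon/nitrogen metabolic network of a proliferating human cell:
#' lumped glycolysis with lactate fermentation, pyruvate import and the TCA
#' cycle (with reversible isocitrate dehydrogenase so reductive carboxylation
#' towards lipogenic citrate is available), oxidative phosphorylation with
#' pseudo-metabolites for the proton gradient (`DPH`, `DPSI`) and the
#' protonmotive force (`PMFm`), the malate-aspartate shuttle, glutaminolysis
#' (glutaminase and glutamate dehydrogenase), serine synthesis and the
#' cytosolic folate cycle (SHMT, glycine cleavage, formate exchange via
#' MTHFD), degradation pathways for arginine, cysteine and the conflated
#' branched/aromatic pools TIV and YFLKW, lumped nucleotide synthesis
#' (converting glutamine to glutamate), citrate-derived lipogenesis and a
#' biomass reaction. Uptake is written on 19 exchange reactions covering the
#' exometabolomically measured metabolites.
#'
#' This network is a synthetic stand-in: it is *not* the published C2M2NF
#' model, whose full reaction list is not redistributed here. It preserves
#' the features the analysis depends on (compartments, pseudo-metabolites,
#' conflated amino-acid pools, Warburg-compatible routes, folate-cycle
#' variability, glutamine-to-glutamate conversion through nucleotide
#' synthesis) at a smaller size.
#'
#' @return a [metabolic_network()] with 52 reactions.
#' @seealso [synthetic_stroma_model()] for the stroma-extended version.
#' @export
synthetic_core_model <- function() {
  mets <- rbind(
    metabolite(c("GLUCx", "LACx", "GLNx", "GLUTx", "SERx", "GLYx", "ASPx",
                 "ARGx", "TIVx", "YFLKWx", "XTPx", "PYRx", "FORx", "CYSx",
                 "METx", "O2x", "CO2x", "NH4x", "BMx"),
               compartment = "external", boundary = TRUE),
    metabolite(c("GLUCc", "PG3", "PYRc", "LACc", "GLNc", "GLUTc", "AKGc",
                 "OAAc", "MALc", "ASPc", "SERc", "GLYc", "ARGc", "TIV",
                 "YFLKW", "CYSc", "MET", "XTPc", "FORc", "THFc", "METHFc",
                 "AcCoAc", "CITc", "LIPID", "ATPc", "ADPc", "NADHc", "NADc",
                 "NH4c", "CO2c", "BMc"),
               compartment = "cytosol"),
    metabolite(c("PYRm", "AcCoAm", "CITm", "AKGm", "OAAm", "MALm", "GLUTm",
                 "NADHm", "NADm", "O2m", "DPH", "DPSI", "PMFm"),
               compartment = "mitochondrion")
  )
  rxns <- list(
    # exchange reactions (sign convention handled by exchange_flux())
    reaction("EX_GLUC", c(GLUCx = -1, GLUCc = 1)),
    reaction("EX_LAC", c(LACc = -1, LACx = 1)),
    reaction("EX_GLN", c(GLNx = -1, GLNc = 1)),
    reaction("EX_GLUT", c(GLUTc = -1, GLUTx = 1), reversible = TRUE),
    reaction("EX_SER", c(SERx = -1, SERc = 1), reversible = TRUE),
    reaction("EX_GLY", c(GLYc = -1, GLYx = 1), reversible = TRUE),
    reaction("EX_ASP", c(ASPx = -1, ASPc = 1), reversible = TRUE),
    reaction("EX_ARG", c(ARGx = -1, ARGc = 1), reversible = TRUE),
    reaction("EX_TIV", c(TIVx = -1, TIV = 1), reversible = TRUE),
    reaction("EX_YFLKW", c(YFLKWx = -1, YFLKW = 1), reversible = TRUE),
    reaction("EX_XTP", c(XTPc = -1, XTPx = 1), reversible = TRUE),
    reaction("EX_PYR", c(PYRc = -1, PYRx = 1), reversible = TRUE),
    reaction("EX_FOR", c(FORc = -1, FORx = 1), reversible = TRUE),
    reaction("EX_CYS", c(CYSx = -1, CYSc = 1), reversible = TRUE),
    reaction("EX_MET", c(METx = -1, MET = 1), reversible = TRUE),
    reaction("EX_O2", c(O2x = -1, O2m = 1)),
    reaction("EX_CO2", c(CO2c = -1, CO2x = 1)),
    reaction("EX_NH4", c(NH4c = -1, NH4x = 1)),
    reaction("EX_BM", c(BMc = -1, BMx = 1)),
    # glycolysis and fermentation
    reaction("GLYCO1", c(GLUCc = -1, NADc = -2, PG3 = 2, NADHc = 2)),
    reaction("GLYCO2", c(PG3 = -1, ADPc = -1, PYRc = 1, ATPc = 1)),
    reaction("LDH", c(PYRc = -1, NADHc = -1, LACc = 1, NADc = 1),
             reversible = TRUE),
    # mitochondrial core
    reaction("PYRT", c(PYRc = -1, PMFm = -1, PYRm = 1)),
    reaction("PDH", c(PYRm = -1, NADm = -1, AcCoAm = 1, CO2c = 1, NADHm = 1)),
    reaction("CS", c(AcCoAm = -1, OAAm = -1, CITm = 1)),
    reaction("IDH", c(CITm = -1, NADm = -1, AKGm = 1, CO2c = 1, NADHm = 1),
             reversible = TRUE),
    reaction("AKGDH", c(AKGm = -1, NADm = -1, MALm = 1, CO2c = 1, NADHm = 1)),
    reaction("MDHm", c(MALm = -1, NADm = -1, OAAm = 1, NADHm = 1),
             reversible = TRUE),
    reaction("RESP", c(NADHm = -1, O2m = -0.5, NADm = 1, DPH = 3, DPSI = 3)),
    reaction("ATPS", c(ADPc = -1, DPH = -2, DPSI = -2, ATPc = 1)),
    reaction("PMF", c(DPH = -1, DPSI = -1, PMFm = 1)),
    # malate-aspartate shuttle / anaplerosis
    reaction("MDHc", c(OAAc = -1, NADHc = -1, MALc = 1, NADc = 1),
             reversible = TRUE),
    reaction("MALT", c(MALc = -1, MALm = 1), reversible = TRUE),
    reaction("AKGT", c(AKGm = -1, AKGc = 1), reversible = TRUE),
    reaction("GOT1", c(AKGc = -1, ASPc = -1, GLUTc = 1, OAAc = 1),
             reversible = TRUE),
    # glutaminolysis
    reaction("GLS", c(GLNc = -1, GLUTc = 1, NH4c = 1)),
    reaction("GLUTT", c(GLUTc = -1, PMFm = -1, GLUTm = 1)),
    reaction("GDH", c(GLUTm = -1, NADm = -1, AKGm = 1, NH4c = 1, NADHm = 1),
             reversible = TRUE),
    # serine, glycine, one-carbon metabolism
    reaction("SERSYNT", c(PG3 = -1, GLUTc = -1, NADc = -1,
                          SERc = 1, AKGc = 1, NADHc = 1)),
    reaction("SHMT1", c(SERc = -1, THFc = -1, GLYc = 1, METHFc = 1),
             reversible = TRUE),
    reaction("GCS", c(GLYc = -1, THFc = -1, NADc = -1,
                      METHFc = 1, CO2c = 1, NH4c = 1, NADHc = 1)),
    reaction("MTHFD1", c(METHFc = -1, NADc = -1, FORc = 1, THFc = 1,
                         NADHc = 1), reversible = TRUE),
    # amino-acid catabolism
    reaction("ARGDG", c(ARGc = -1, AKGc = -1, GLUTc = 2, NH4c = 2)),
    reaction("CYSDG", c(CYSc = -1, PYRc = 1, NH4c = 1)),
    reaction("TIVDG", c(TIV = -1, AKGc = -1, NADm = -1,
                        GLUTc = 1, AcCoAm = 1, CO2c = 1, NADHm = 1)),
    reaction("YFLKWDG", c(YFLKW = -1, AKGc = -1, NADm = -1,
                          GLUTc = 1, AcCoAm = 1, CO2c = 1, NADHm = 1)),
    # nucleotide synthesis (glutamine amidotransferase steps release
    # glutamate; one-carbon units from the folate cycle)
    reaction("NUC", c(GLNc = -2, ASPc = -1, GLYc = -1, METHFc = -1,
                      GLUCc = -0.5, ATPc = -4,
                      XTPc = 1, GLUTc = 2, THFc = 1, ADPc = 4)),
    # lipogenesis from citrate
    reaction("CITT", c(CITm = -1, PMFm = -1, CITc = 1)),
    reaction("ACL", c(CITc = -1, ATPc = -1, AcCoAc = 1, OAAc = 1, ADPc = 1)),
    reaction("FAS", c(AcCoAc = -8, ATPc = -7, NADHc = -14,
                      LIPID = 1, ADPc = 7, NADc = 14)),
    # biomass (tumoral growth); one unit is a cell-growth quantum, a much
    # larger draw on precursors than one secreted protein molecule
    reaction("BM", c(GLYc = -7, SERc = -5, ASPc = -6, GLUTc = -6,
                     GLNc = -4, ARGc = -3, TIV = -6, YFLKW = -7,
                     CYSc = -1, MET = -1, XTPc = -10, LIPID = -8,
                     ATPc = -1200, BMc = 1, ADPc = 1200))
  )
  metabolic_network(mets, rxns)
}

#' Synthetic stroma-extended model
#'
#' [synthetic_core_model()] extended with [build_stroma_extension()]:
#' collagen synthesis, IL1-beta/TNF-alpha/VEGF-A production, the stroma
#' lumping block, and transport/metabolism of proline, histidine, alanine
#' and asparagine. This is the network the packaged analyses run on.
#'
#' @return a [metabolic_network()] with 74 reactions, 24 of them exchanges.
#' @export
synthetic_stroma_model <- function() {
  build_stroma_extension(synthetic_core_model())
}

#' Default mapping from exometabolomic metabolite names to model ids
#'
#' Maps the measurement table's metabolite keys (e.g. `"glucose"`) to the
#' boundary species ids of the packaged synthetic model, for use with
#' [exchange_flux()] and the scoring functions. Boundary ids are used
#' (rather than internal ids) so the mapping stays valid on compressed
#' networks. Supply your own mapping for models with different id
#' conventions.
#'
#' @return named character vector.
#' @export
default_exchange_aliases <- function() {
  c(glucose = "GLUCx", lactate = "LACx", glutamine = "GLNx",
    glutamate = "GLUTx", serine = "SERx", glycine = "GLYx",
    alanine = "ALAx", proline = "PROx", asp_asn = "ASPx",
    arginine = "ARGx", tiv = "TIVx", yflkw = "YFLKWx", xtp = "XTPx",
    pyruvate = "PYRx", formate = "FORx", histidine = "HISx",
    cysteine = "CYSx", methionine = "METx",
    biomass = "BMx", collagen = "Collagenx", stroma = "Stromax")
}
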