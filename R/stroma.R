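#' Amino-acid compositions of the stroma marker proteins
#'
#' Residue counts per amino-acid pool for IL1-beta (269 residues),
#' TNF-alpha (233) and VEGF-A (232), on the conflated pool alphabet used by
#' the core model (TIV = Thr/Ile/Val, YFLKW = Tyr/Phe/Leu/Lys/Trp). Stored
#' as packaged constants rather than recomputed from sequence databases, so
#' the built reactions are reproducible across sequence-database versions.
#'
#' @return named list with elements `IL1B`, `TNFA`, `VEGFA`, each a list
#'   with `counts` (named integer vector) and `length`.
#' @export
protein_compositions <- function() {
  list(
    IL1B = list(length = 269L, counts = c(
      MET = 12L, ALAc = 13L, GLUTc = 21L, TIV = 35L, PROc = 15L,
      YFLKW = 74L, SERc = 21L, GLYc = 13L, ASNc = 12L, ASPc = 20L,
      GLNc = 18L, CYSc = 5L, ARGc = 6L, HISc = 4L)),
    TNFA = list(length = 233L, counts = c(
      MET = 2L, SERc = 20L, TIV = 38L, GLUTc = 16L, ARGc = 14L,
      ASPc = 7L, YFLKW = 57L, ALAc = 19L, PROc = 15L, GLYc = 17L,
      GLNc = 13L, CYSc = 4L, HISc = 4L, ASNc = 7L)),
    VEGFA = list(length = 232L, counts = c(
      MET = 8L, ASNc = 7L, YFLKW = 55L, SERc = 15L, TIV = 25L,
      HISc = 11L, ALAc = 8L, GLNc = 13L, PROc = 15L, GLUTc = 16L,
      GLYc = 14L, ASPc = 8L, ARGc = 19L, CYSc = 18L))
  )
}

# amino-acid pool ids a protein synthesis reaction may draw on
AA_POOLS <- c("MET", "ALAc", "GLUTc", "TIV", "PROc", "YFLKW", "SERc",
              "GLYc", "ASNc", "ASPc", "GLNc", "CYSc", "ARGc", "HISc")

# printed-id aliases: the model text uses both suffixed and unsuffixed forms
normalize_pool_id <- function(ids) {
  alias <- c(METc = "MET", TIVc = "TIV", YFLKWc = "YFLKW",
             Gly = "GLYc", Pro = "PROc", Hyp = "HYPc")
  out <- ifelse(ids %in% names(alias), alias[ids], ids)
  unname(out)
}

#' Build a protein synthesis reaction from a residue composition
#'
#' The reaction consumes amino-acid pools in proportions `count / length`
#' (so reactant coefficients sum to one) and produces the protein with
#' coefficient `1 / length`: one unit of reaction flux corresponds to one
#' amino acid polymerized, and `length` units produce one protein molecule.
#'
#' @param name protein metabolite id (also the reaction id).
#' @param composition named integer vector of residue counts per pool id;
#'   pool ids must come from the model's amino-acid pool alphabet.
#' @param length protein length in residues; must equal `sum(composition)`.
#' @return a [reaction()], irreversible.
#' @export
protein_synthesis_reaction <- function(name, composition, length) {
  names(composition) <- normalize_pool_id(names(composition))
  bad <- setdiff(names(composition), AA_POOLS)
  if (base::length(bad)) {
    stop("unknown amino-acid pool id(s): ", paste(bad, collapse = ", "))
  }
  if (sum(composition) != length) {
    stop("residue counts sum to ", sum(composition),
         " but protein length is ", length)
  }
  sto <- c(-composition / length, stats::setNames(1 / length, name))
  reaction(name, sto, reversible = FALSE)
}

#' Extend a core metabolic model with tumoral stroma formation
#'
#' Adds to `base`: the collagen synthesis block (XYAAS building the
#' equiprobable X-Y amino-acid pool, CBS assembling 100-residue collagen
#' bricks as 33% glycine, 50% XYAA, 8.5% proline, 8.5% hydroxyproline, and
#' COLLAG condensing 100 bricks into one collagen polypeptide); protein
#' synthesis reactions for IL1-beta, TNF-alpha and VEGF-A from their residue
#' compositions; the stroma lumping block (FACT, INF1, INF2, STROMA)
#' requiring one inflammation marker plus the growth factor; exchange
#' reactions for collagen and stroma; and transporter/degradation pathways
#' for the amino acids absent from the core model (proline, histidine,
#' alanine, asparagine), including proline synthesis and hydroxylation,
#' histidine degradation through the folate cycle, alanine transaminase,
#' asparagine synthetase and asparaginase.
#'
#' @param base a [metabolic_network()] containing the core amino-acid pool
#'   metabolites (see [protein_compositions()]) and the cofactors the added
#'   pathways use.
#' @return a new, larger [metabolic_network()].
#' @export
build_stroma_extension <- function(base) {
  required <- c("MET", "GLUTc", "TIV", "YFLKW", "SERc", "GLYc", "ASPc",
                "GLNc", "CYSc", "ARGc",
                "PYRc", "AKGc", "ATPc", "ADPc", "NADHc", "NADc",
                "NH4c", "THFc", "METHFc")
  missing <- setdiff(required, base$metabolites$id)
  if (length(missing)) {
    stop("base model is missing required metabolite(s): ",
         paste(missing, collapse = ", "))
  }
  clash <- intersect(c("PROc", "HYPc", "HISc", "ALAc", "ASNc", "XYAA",
                       "CBrick", "Collagen", "IL1B", "TNFA", "VEGFA",
                       "Inflam", "GrowthFactor", "Stroma"),
                     base$metabolites$id)
  if (length(clash)) {
    stop("base model already contains extension metabolite(s): ",
         paste(clash, collapse = ", "))
  }
  mets <- rbind(
    base$metabolites,
    metabolite(c("PROc", "HYPc", "HISc", "ALAc", "ASNc", "XYAA", "CBrick",
                 "Collagen", "IL1B", "TNFA", "VEGFA", "Inflam",
                 "GrowthFactor", "Stroma"),
               compartment = "cytosol"),
    metabolite(c("PROx", "HISx", "ALAx", "Collagenx", "Stromax"),
               compartment = "external", boundary = TRUE)
  )
  comp <- protein_compositions()
  ext <- list(
    # amino acids missing from the core model: transport and metabolism
    reaction("EX_PRO", c(PROx = -1, PROc = 1), reversible = TRUE),
    reaction("EX_HIS", c(HISx = -1, HISc = 1), reversible = TRUE),
    reaction("EX_ALA", c(ALAc = -1, ALAx = 1), reversible = TRUE),
    reaction("ALATA", c(PYRc = -1, GLUTc = -1, ALAc = 1, AKGc = 1),
             reversible = TRUE),
    reaction("ASNS", c(ASPc = -1, GLNc = -1, ATPc = -1,
                       ASNc = 1, GLUTc = 1, ADPc = 1)),
    reaction("ASNASE", c(ASNc = -1, ASPc = 1, NH4c = 1)),
    reaction("PROS", c(GLUTc = -1, ATPc = -1, NADHc = -2,
                       PROc = 1, ADPc = 1, NADc = 2)),
    reaction("PRODG", c(PROc = -1, NADc = -1, GLUTc = 1, NADHc = 1)),
    reaction("HPRO", c(PROc = -1, HYPc = 1)),
    reaction("HISDG", c(HISc = -1, THFc = -1,
                        GLUTc = 1, NH4c = 2, METHFc = 1)),
    # collagen synthesis
    reaction("XYAAS", c(ALAc = -1, ARGc = -1, SERc = -1, TIV = -1,
                        YFLKW = -1, GLNc = -1, ASPc = -1, GLUTc = -1,
                        XYAA = 14)),
    reaction("CBS", c(GLYc = -0.33, XYAA = -0.50, PROc = -0.085,
                      HYPc = -0.085, CBrick = 1)),
    reaction("COLLAG", c(CBrick = -100, Collagen = 1)),
    # stroma marker proteins
    protein_synthesis_reaction("IL1B", comp$IL1B$counts, comp$IL1B$length),
    protein_synthesis_reaction("TNFA", comp$TNFA$counts, comp$TNFA$length),
    protein_synthesis_reaction("VEGFA", comp$VEGFA$counts, comp$VEGFA$length),
    reaction("FACT", c(VEGFA = -1, GrowthFactor = 1)),
    reaction("INF1", c(IL1B = -1, Inflam = 1)),
    reaction("INF2", c(TNFA = -1, Inflam = 1)),
    reaction("STROMA", c(Inflam = -1, GrowthFactor = -1, Stroma = 1)),
    reaction("EX_COLLAGEN", c(Collagen = -1, Collagenx = 1)),
    reaction("EX_STROMA", c(Stroma = -1, Stromax = 1))
  )
  metabolic_network(mets, c(base$reactions, ext))
}
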