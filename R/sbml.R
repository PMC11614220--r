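#' Read a metabolic network from SBML
#'
#' Parses an SBML Level 3 (core) document into a [metabolic_network()].
#' Boundary species are identified by their `boundaryCondition` attribute or
#' by membership in the external compartment when the flag is absent. Flux
#' bounds are read from reaction-level local parameters named `LOWER_BOUND`
#' and `UPPER_BOUND` when present, else defaulted from reversibility.
#'
#' Compartment ids are mapped onto the three model compartments; common
#' abbreviations (`e`/`ext`/`x` for external, `c`/`cyt` for cytosol,
#' `m`/`mit`/`mito` for mitochondrion) are accepted. Unknown compartments
#' are a validation error.
#'
#' @param path path to an SBML file.
#' @return a [metabolic_network()] with deterministic metabolite/reaction
#'   order (document order).
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed SBML: ", conditionMessage(e))
  })
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing")) stop("malformed SBML: no <model> element")

  species <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (!length(species)) stop("malformed SBML: no <species> elements")
  sid <- xml2::xml_attr(species, "id")
  sname <- xml2::xml_attr(species, "name")
  scomp <- vapply(xml2::xml_attr(species, "compartment"), map_compartment, "")
  sbound <- xml2::xml_attr(species, "boundaryCondition")
  sbound <- !is.na(sbound) & sbound %in% c("true", "1")
  mets <- data.frame(
    id = sid,
    name = ifelse(is.na(sname), sid, sname),
    compartment = unname(scomp),
    boundary = sbound | (is.na(xml2::xml_attr(species, "boundaryCondition")) &
                           scomp == "external"),
    stringsAsFactors = FALSE
  )

  rxn_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  reactions <- lapply(rxn_nodes, function(node) {
    rid <- xml2::xml_attr(node, "id")
    if (is.na(rid)) stop("malformed SBML: reaction without id")
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    sto <- numeric(0)
    for (ref in xml2::xml_find_all(node, "./listOfReactants/speciesReference")) {
      sp <- xml2::xml_attr(ref, "species")
      k <- as.numeric(xml2::xml_attr(ref, "stoichiometry"))
      if (is.na(k)) k <- 1
      sto[sp] <- (if (sp %in% names(sto)) sto[[sp]] else 0) - k
    }
    for (ref in xml2::xml_find_all(node, "./listOfProducts/speciesReference")) {
      sp <- xml2::xml_attr(ref, "species")
      k <- as.numeric(xml2::xml_attr(ref, "stoichiometry"))
      if (is.na(k)) k <- 1
      sto[sp] <- (if (sp %in% names(sto)) sto[[sp]] else 0) + k
    }
    pars <- xml2::xml_find_all(node, ".//localParameter | .//parameter")
    pid <- xml2::xml_attr(pars, "id")
    pval <- as.numeric(xml2::xml_attr(pars, "value"))
    lb <- if ("LOWER_BOUND" %in% pid) pval[match("LOWER_BOUND", pid)] else if (rev) -1000 else 0
    ub <- if ("UPPER_BOUND" %in% pid) pval[match("UPPER_BOUND", pid)] else 1000
    reaction(rid, sto, reversible = rev, lb = lb, ub = ub)
  })
  metabolic_network(mets, reactions)
}

map_compartment <- function(x) {
  if (is.na(x)) stop("species without compartment")
  key <- tolower(x)
  out <- switch(key,
    "external" = , "e" = , "ext" = , "x" = , "extracellular" = "external",
    "cytosol" = , "c" = , "cyt" = , "cytoplasm" = , "cytosolic" = "cytosol",
    "mitochondrion" = , "m" = , "mit" = , "mito" = ,
    "mitochondria" = "mitochondrion",
    NULL)
  if (is.null(out)) stop("unknown compartment: ", x)
  out
}

#' Write a metabolic network to SBML Level 3 Version 1
#'
#' Inverse of [read_sbml()]: `read_sbml(write_sbml(net, f))` reproduces the
#' stoichiometry, reversibility and flux bounds of `net`. Boundary species
#' carry `boundaryCondition="true"`; flux bounds are written as reaction
#' local parameters `LOWER_BOUND`/`UPPER_BOUND`.
#'
#' @param net a [metabolic_network()].
#' @param path output file path.
#' @export
write_sbml <- function(net, path) {
  comp_id <- c(external = "e", cytosol = "c", mitochondrion = "m")
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '  <model id="model">',
    '    <listOfCompartments>',
    sprintf('      <compartment id="%s" name="%s" constant="true"/>',
            comp_id, names(comp_id)),
    '    </listOfCompartments>',
    '    <listOfSpecies>'
  )
  m <- net$metabolites
  lines <- c(lines, sprintf(
    '      <species id="%s" name="%s" compartment="%s" boundaryCondition="%s" hasOnlySubstanceUnits="false" constant="false"/>',
    m$id, xml_escape(m$name), comp_id[m$compartment],
    ifelse(m$boundary, "true", "false")))
  lines <- c(lines, '    </listOfSpecies>', '    <listOfReactions>')
  for (r in net$reactions) {
    lines <- c(lines, sprintf('      <reaction id="%s" reversible="%s" fast="false">',
                              r$id, if (r$reversible) "true" else "false"))
    reac <- r$stoich[r$stoich < 0]
    prod <- r$stoich[r$stoich > 0]
    if (length(reac)) {
      lines <- c(lines, '        <listOfReactants>',
                 sprintf('          <speciesReference species="%s" stoichiometry="%.12g" constant="true"/>',
                         names(reac), -unname(reac)),
                 '        </listOfReactants>')
    }
    if (length(prod)) {
      lines <- c(lines, '        <listOfProducts>',
                 sprintf('          <speciesReference species="%s" stoichiometry="%.12g" constant="true"/>',
                         names(prod), unname(prod)),
                 '        </listOfProducts>')
    }
    lines <- c(lines,
               '        <kineticLaw>',
               '          <listOfLocalParameters>',
               sprintf('            <localParameter id="LOWER_BOUND" value="%.12g"/>', r$lb),
               sprintf('            <localParameter id="UPPER_BOUND" value="%.12g"/>', r$ub),
               '          </listOfLocalParameters>',
               '        </kineticLaw>',
               '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>', '  </model>', '</sbml>')
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot write SBML to ", path, ": ", conditionMessage(e))
  })
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}
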