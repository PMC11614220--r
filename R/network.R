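#' Stoichiometric network container
#'
#' A `metabolic_network` holds an ordered metabolite table and an ordered
#' reaction list, in the style of constraint-based modelling tools. The
#' steady-state balance `N v = 0` is taken over *internal* (non-boundary)
#' metabolites only; boundary species (typically in the external
#' compartment, flagged `boundary = TRUE`) are sources/sinks and excluded
#' from the balance.
#'
#' @param metabolites data frame with columns `id`, `name`, `compartment`
#'   (one of `"external"`, `"cytosol"`, `"mitochondrion"`) and `boundary`
#'   (logical).
#' @param reactions list of reactions built with [reaction()].
#' @return object of class `metabolic_network` with elements `metabolites`,
#'   `reactions`, and accessors via [stoich_matrix()] etc.
#' @seealso [reaction()], [stoich_matrix()], [exchange_reactions()]
#' @export
metabolic_network <- function(metabolites, reactions) {
  stopifnot(is.data.frame(metabolites),
            all(c("id", "name", "compartment", "boundary") %in% names(metabolites)))
  metabolites$id <- as.character(metabolites$id)
  if (anyDuplicated(metabolites$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  }
  bad_comp <- setdiff(unique(metabolites$compartment), COMPARTMENTS)
  if (length(bad_comp)) {
    stop("unknown compartment(s): ", paste(bad_comp, collapse = ", "))
  }
  rids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(rids)) {
    stop("duplicate reaction ids: ", paste(rids[duplicated(rids)], collapse = ", "))
  }
  for (r in reactions) {
    missing <- setdiff(names(r$stoich), metabolites$id)
    if (length(missing)) {
      stop("reaction ", r$id, " references unknown metabolite(s): ",
           paste(missing, collapse = ", "))
    }
  }
  net <- structure(
    list(metabolites = metabolites, reactions = reactions),
    class = "metabolic_network"
  )
  net
}

COMPARTMENTS <- c("external", "cytosol", "mitochondrion")

#' Construct a reaction
#'
#' @param id reaction identifier.
#' @param stoich named numeric vector, metabolite id -> signed coefficient
#'   (negative = consumed, positive = produced).
#' @param reversible logical; irreversible reactions require `lb >= 0`.
#' @param lb,ub flux bounds in model units.
#' @export
reaction <- function(id, stoich, reversible = FALSE,
                     lb = if (reversible) -1000 else 0, ub = 1000) {
  stoich <- stoich[stoich != 0]
  if (!length(stoich)) stop("reaction ", id, " has no nonzero coefficient")
  if (!reversible && lb < 0) stop("irreversible reaction ", id, " must have lb >= 0")
  if (is.null(names(stoich)) || any(!nzchar(names(stoich)))) {
    stop("stoichiometry must be a named vector")
  }
  list(id = as.character(id), stoich = stoich,
       reversible = isTRUE(reversible), lb = lb, ub = ub)
}

#' Metabolite table helper
#' @param id,name,compartment,boundary vectors, recycled to common length.
#' @export
metabolite <- function(id, name = id, compartment = "cytosol", boundary = FALSE) {
  data.frame(id = id, name = name, compartment = compartment,
             boundary = boundary, stringsAsFactors = FALSE)
}

#' @export
print.metabolic_network <- function(x, ...) {
  nint <- sum(!x$metabolites$boundary)
  cat("metabolic_network:", length(x$reactions), "reactions,",
      nrow(x$metabolites), "metabolites (", nint, "internal ),",
      length(exchange_reactions(x)), "exchange\n")
  invisible(x)
}

reaction_ids <- function(net) vapply(net$reactions, `[[`, "", "id")

reaction_by_id <- function(net, id) {
  i <- match(id, reaction_ids(net))
  if (is.na(i)) stop("no reaction with id ", id)
  net$reactions[[i]]
}

internal_metabolites <- function(net) {
  net$metabolites$id[!net$metabolites$boundary]
}

#' Stoichiometric matrix
#'
#' Rows are metabolites (internal only by default, matching the steady-state
#' balance), columns are reactions, in network order.
#'
#' @param net a [metabolic_network()].
#' @param internal_only drop boundary metabolite rows (default TRUE).
#' @export
stoich_matrix <- function(net, internal_only = TRUE) {
  mets <- if (internal_only) internal_metabolites(net) else net$metabolites$id
  rids <- reaction_ids(net)
  N <- matrix(0, length(mets), length(rids), dimnames = list(mets, rids))
  for (j in seq_along(net$reactions)) {
    s <- net$reactions[[j]]$stoich
    keep <- names(s) %in% mets
    if (any(keep)) N[names(s)[keep], j] <- s[keep]
  }
  N
}

#' Exchange reactions of a network
#'
#' A reaction is an exchange if it touches exactly one internal metabolite
#' (its other participants, if any, being boundary species).
#'
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(net) {
  internal <- internal_metabolites(net)
  is_ex <- vapply(net$reactions, function(r) {
    sum(names(r$stoich) %in% internal) == 1L
  }, NA)
  reaction_ids(net)[is_ex]
}

# id of the single internal metabolite an exchange reaction touches
exchange_partner <- function(net, rid) {
  r <- reaction_by_id(net, rid)
  internal <- internal_metabolites(net)
  ids <- names(r$stoich)[names(r$stoich) %in% internal]
  if (length(ids) != 1L) stop("reaction ", rid, " is not an exchange reaction")
  ids
}

# exchange reaction id for an internal metabolite (error if none/ambiguous)
exchange_for_metabolite <- function(net, met) {
  ex <- exchange_reactions(net)
  hit <- ex[vapply(ex, function(rid) exchange_partner(net, rid) == met, NA)]
  if (!length(hit)) stop("no exchange reaction for metabolite ", met)
  hit[[1L]]
}

#' Signed exchange flux of a metabolite
#'
#' Returns the external exchange rate of `metabolite` implied by the flux
#' vector `v`, normalized so that uptake is negative and secretion positive
#' regardless of the orientation in which the exchange reaction is written
#' in the model file.
#'
#' When `metabolite` resolves to a boundary species, the exchange flux is
#' its net production rate summed over all reactions touching it — this
#' works unchanged on compressed networks, where exchange reactions may
#' have been merged into enzyme subsets (and the internal partner species
#' may have cancelled out of the network entirely). When it resolves to an
#' internal metabolite, its unique exchange reaction is located first.
#'
#' @param v named numeric flux vector (names are reaction ids) or a
#'   [flux_mode()].
#' @param metabolite metabolite id — boundary (e.g. `"GLUCx"`) or internal
#'   (e.g. `"GLUCc"`) — or an alias resolvable through `aliases`.
#' @param net a [metabolic_network()].
#' @param aliases optional named character vector mapping external names
#'   (e.g. `"glucose"`) to metabolite ids.
#' @export
exchange_flux <- function(v, metabolite, net, aliases = NULL) {
  if (inherits(v, "flux_mode")) v <- v$v
  if (!is.null(aliases) && metabolite %in% names(aliases)) {
    metabolite <- aliases[[metabolite]]
  }
  i <- match(metabolite, net$metabolites$id)
  if (is.na(i)) stop("no metabolite with id ", metabolite)
  if (net$metabolites$boundary[i]) {
    # production of the boundary species = secretion (positive)
    total <- 0
    for (r in net$reactions) {
      if (metabolite %in% names(r$stoich) && r$id %in% names(v)) {
        total <- total + r$stoich[[metabolite]] * v[[r$id]]
      }
    }
    return(total)
  }
  rid <- exchange_for_metabolite(net, metabolite)
  r <- reaction_by_id(net, rid)
  c_int <- r$stoich[[metabolite]]
  f <- if (rid %in% names(v)) v[[rid]] else 0
  # positive internal production (c_int * f > 0) is uptake, hence negative
  -c_int * f
}

# reactions touching a boundary species, with their signed coefficients
boundary_touchers <- function(net, met) {
  hits <- Filter(function(r) met %in% names(r$stoich), net$reactions)
  list(rxn = vapply(hits, `[[`, "", "id"),
       coef = vapply(hits, function(r) r$stoich[[met]], 0))
}

#' Flux mode
#'
#' A steady-state flux vector together with its support. `verified_elementary`
#' records whether the stoichiometric rank test has been applied successfully.
#'
#' @param v named numeric vector over (a subset of) the network's reactions.
#' @param net the network the mode lives on (used to fill missing entries
#'   with zero and to order entries deterministically).
#' @param verified_elementary logical flag.
#' @param tol relative tolerance for support membership.
#' @export
flux_mode <- function(v, net, verified_elementary = FALSE, tol = 1e-9) {
  rids <- reaction_ids(net)
  unknown <- setdiff(names(v), rids)
  if (length(unknown)) {
    stop("flux vector references unknown reaction(s): ",
         paste(unknown, collapse = ", "))
  }
  full <- stats::setNames(numeric(length(rids)), rids)
  full[names(v)] <- as.numeric(v)
  scale <- max(abs(full), 0)
  supp <- if (scale > 0) rids[abs(full) > tol * scale] else character()
  structure(list(v = full, support = supp,
                 verified_elementary = isTRUE(verified_elementary)),
            class = "flux_mode")
}

#' @export
print.flux_mode <- function(x, ...) {
  cat("flux_mode: support", length(x$support), "reactions",
      if (x$verified_elementary) "(verified elementary)" else "", "\n")
  nz <- x$v[x$v != 0]
  print(round(nz, 6))
  invisible(x)
}

#' Export the stoichiometric matrix as CSV
#'
#' Metabolite rows by reaction columns, with a header row of reaction ids.
#' @export
write_stoich_csv <- function(net, path, internal_only = FALSE) {
  N <- stoich_matrix(net, internal_only = internal_only)
  utils::write.csv(as.data.frame(N), path, row.names = TRUE)
  invisible(path)
}

#' Normalize a flux vector so its largest absolute entry is one
#' @param v numeric flux vector.
#' @export
normalize_flux <- function(v) {
  m <- max(abs(v))
  if (m > 0) v / m else v
}
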