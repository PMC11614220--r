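#' Find blocked reactions
#'
#' A reaction is blocked when its flux is zero in every bounded steady-state
#' flux distribution: `max |v_r| = 0` over `{v : N v = 0, irreversibility
#' respected, |v_r| <= bound}`. Detection combines a nullspace prescreen
#' (a reaction whose row in a kernel basis of N is zero can carry no
#' steady-state flux at all) with flux-variability LPs for the remaining
#' candidates; any reaction observed active in some LP solution is certified
#' unblocked without further LPs.
#'
#' @param net a [metabolic_network()].
#' @param bound box bound used to keep the LPs bounded.
#' @param tol activity tolerance relative to `bound`.
#' @return character vector of blocked reaction ids (possibly empty).
#' @export
find_blocked_reactions <- function(net, bound = 1000, tol = 1e-9) {
  N <- stoich_matrix(net)
  rids <- colnames(N)
  n <- length(rids)
  lb <- ifelse(vapply(net$reactions, `[[`, NA, "reversible"), -bound, 0)
  ub <- rep(bound, n)
  K <- null_space(N)
  if (ncol(K) == 0L) return(rids)
  row_mag <- sqrt(rowSums(K^2))
  blocked <- row_mag < 1e-9
  unblocked <- rep(FALSE, n)
  abs_tol <- tol * bound
  for (j in seq_len(n)) {
    if (blocked[j] || unblocked[j]) next
    obj <- numeric(n)
    obj[j] <- 1
    sol <- solve_lp(obj, A_eq = N, b_eq = rep(0, nrow(N)),
                    lb = lb, ub = ub, maximize = TRUE)
    if (sol$status == "optimal" && sol$objective > abs_tol) {
      unblocked <- unblocked | abs(sol$x) > abs_tol
      next
    }
    if (lb[j] < 0) {
      sol <- solve_lp(obj, A_eq = N, b_eq = rep(0, nrow(N)),
                      lb = lb, ub = ub, maximize = FALSE)
      if (sol$status == "optimal" && sol$objective < -abs_tol) {
        unblocked <- unblocked | abs(sol$x) > abs_tol
        next
      }
    }
    blocked[j] <- TRUE
  }
  rids[blocked]
}

#' Compress a network into enzyme subsets
#'
#' Removes blocked reactions, then merges reactions whose fluxes are in a
#' fixed ratio in every steady state ("enzyme subsets"). Fixed ratios are
#' detected from a kernel basis of the internal stoichiometric matrix: two
#' reactions belong to one subset when their kernel rows are proportional
#' (cosine similarity above `1 - 1e-9`). Each subset becomes one compressed
#' reaction with ratio-scaled, summed stoichiometry, oriented so that its
#' irreversible members run forward; metabolites left untouched by any
#' remaining reaction are dropped. Flux modes of the compressed network map
#' losslessly back to the original through [decompress()].
#'
#' @param net a [metabolic_network()].
#' @param bound box bound for blocked-reaction detection.
#' @return list with `network` (compressed [metabolic_network()]) and `map`
#'   (a `compression_map`: `subsets` of members and ratio coefficients, and
#'   `blocked` reaction ids).
#' @export
compress <- function(net, bound = 1000) {
  blocked <- find_blocked_reactions(net, bound = bound)
  keep <- setdiff(reaction_ids(net), blocked)
  rxns <- net$reactions[match(keep, reaction_ids(net))]
  if (!length(rxns)) {
    map <- structure(list(subsets = list(), blocked = blocked),
                     class = "compression_map")
    empty <- metabolic_network(net$metabolites[0, ], list())
    return(list(network = empty, map = map))
  }
  sub <- metabolic_network(net$metabolites, rxns)
  N <- stoich_matrix(sub)
  K <- null_space(N)
  nk <- nrow(K)
  # group rows with proportional kernel rows
  unit <- K / sqrt(rowSums(K^2))
  cosim <- abs(unit %*% t(unit))
  group <- rep(NA_integer_, nk)
  g <- 0L
  for (i in seq_len(nk)) {
    if (!is.na(group[i])) next
    g <- g + 1L
    members <- which(is.na(group) & cosim[i, ] > 1 - 1e-9)
    group[members] <- g
  }
  subsets <- list()
  new_rxns <- list()
  for (gi in seq_len(g)) {
    idx <- which(group == gi)
    rep_i <- idx[1L]
    ratios <- as.vector(K[idx, , drop = FALSE] %*% K[rep_i, ]) /
      sum(K[rep_i, ]^2)
    members <- vapply(rxns[idx], `[[`, "", "id")
    # orientation: irreversible members must run forward
    irrev <- !vapply(rxns[idx], `[[`, NA, "reversible")
    need_pos <- irrev & ratios > 0
    need_neg <- irrev & ratios < 0
    if (any(need_pos) && any(need_neg)) {
      stop("inconsistent enzyme subset orientation for: ",
           paste(members, collapse = ", "),
           " (should have been removed as blocked)")
    }
    if (any(need_neg)) ratios <- -ratios
    sto <- numeric(0)
    for (k in seq_along(idx)) {
      s <- rxns[[idx[k]]]$stoich * ratios[k]
      for (m in names(s)) sto[m] <- (if (m %in% names(sto)) sto[[m]] else 0) + s[[m]]
    }
    sto <- sto[abs(sto) > 1e-10]
    rid <- if (length(members) == 1L) members else paste(members, collapse = "__")
    reversible <- all(!irrev)
    new_rxns[[gi]] <- reaction(rid, sto, reversible = reversible)
    subsets[[gi]] <- list(id = rid, members = members, ratios = ratios)
  }
  used <- unique(unlist(lapply(new_rxns, function(r) names(r$stoich))))
  mets <- net$metabolites[net$metabolites$id %in% used, , drop = FALSE]
  rownames(mets) <- NULL
  compressed <- metabolic_network(mets, new_rxns)
  map <- structure(list(subsets = subsets, blocked = blocked),
                   class = "compression_map")
  list(network = compressed, map = map)
}

#' @export
print.compression_map <- function(x, ...) {
  merged <- sum(vapply(x$subsets, function(s) length(s$members), 0L) > 1L)
  cat("compression_map:", length(x$subsets), "subsets (", merged,
      "merged ),", length(x$blocked), "blocked reactions\n")
  invisible(x)
}

#' Decompress a flux vector from the compressed to the original network
#'
#' Each original reaction receives its subset's flux scaled by its ratio
#' coefficient; blocked reactions receive zero.
#'
#' @param v named numeric flux vector over compressed reaction ids, or a
#'   [flux_mode()].
#' @param map a `compression_map` from [compress()].
#' @param net original network (used to order and complete the result).
#' @return named numeric vector over the original network's reactions (or a
#'   [flux_mode()] when `net` is supplied and `v` was one).
#' @export
decompress <- function(v, map, net = NULL) {
  was_mode <- inherits(v, "flux_mode")
  if (was_mode) v <- v$v
  known <- vapply(map$subsets, `[[`, "", "id")
  unknown <- setdiff(names(v), known)
  if (length(unknown)) {
    stop("unknown compressed reaction id(s): ", paste(unknown, collapse = ", "))
  }
  out <- numeric(0)
  for (s in map$subsets) {
    f <- if (s$id %in% names(v)) v[[s$id]] else 0
    out[s$members] <- f * s$ratios
  }
  out[map$blocked] <- 0
  if (!is.null(net)) {
    full <- stats::setNames(numeric(length(net$reactions)), reaction_ids(net))
    full[names(out)] <- out
    if (was_mode) return(flux_mode(full, net, verified_elementary = FALSE))
    return(full)
  }
  out
}

#' Serialize a compression map to JSON
#' @export
write_compression_map <- function(map, path) {
  jsonlite::write_json(
    list(subsets = lapply(map$subsets, function(s)
      list(id = s$id, members = s$members, ratios = s$ratios)),
      blocked = map$blocked),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
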