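#' Split reversible reactions into irreversible forward/backward pairs
#'
#' Standard preprocessing for flux-mode computation: each reversible
#' reaction `r` becomes `r` (forward, as written) and `r_rev` (negated
#' stoichiometry), both irreversible. The spurious two-cycle `{r, r_rev}`
#' this creates is excluded downstream by the enumeration routines.
#'
#' @param net a [metabolic_network()].
#' @return list with `network` (all-irreversible network), and `pairs`
#'   (data frame with columns `fwd`, `bwd` for each split reaction).
#' @export
split_reversibles <- function(net) {
  rxns <- list()
  fwd <- character()
  bwd <- character()
  for (r in net$reactions) {
    rxns[[length(rxns) + 1L]] <- reaction(r$id, r$stoich, reversible = FALSE,
                                          lb = 0, ub = r$ub)
    if (r$reversible) {
      rid2 <- paste0(r$id, "_rev")
      rxns[[length(rxns) + 1L]] <- reaction(rid2, -r$stoich,
                                            reversible = FALSE,
                                            lb = 0, ub = abs(r$lb))
      fwd <- c(fwd, r$id)
      bwd <- c(bwd, rid2)
    }
  }
  list(network = metabolic_network(net$metabolites, rxns),
       pairs = data.frame(fwd = fwd, bwd = bwd, stringsAsFactors = FALSE))
}

# net flux vector on the original network from a split-network vector
unsplit_flux <- function(v_split, net, pairs) {
  rids <- reaction_ids(net)
  v <- stats::setNames(numeric(length(rids)), rids)
  common <- intersect(names(v_split), rids)
  v[common] <- v_split[common]
  if (nrow(pairs)) {
    present <- pairs$bwd %in% names(v_split)
    v[pairs$fwd[present]] <- v[pairs$fwd[present]] - v_split[pairs$bwd[present]]
  }
  v
}

#' Steady-state test
#'
#' TRUE when `max |N v|` over internal metabolites is at most
#' `tol * max(1, max |v|)`.
#'
#' @param v named flux vector or [flux_mode()].
#' @param net a [metabolic_network()].
#' @param tol relative tolerance.
#' @export
is_steady_state <- function(v, net, tol = 1e-6) {
  if (inherits(v, "flux_mode")) v <- v$v
  stopifnot(tol > 0)
  N <- stoich_matrix(net)
  x <- stats::setNames(numeric(ncol(N)), colnames(N))
  x[intersect(names(v), names(x))] <- v[intersect(names(v), names(x))]
  imbalance <- max(abs(N %*% x), 0)
  imbalance <= tol * max(1, max(abs(x)))
}

#' Elementarity rank test
#'
#' A steady-state flux vector is elementary iff the stoichiometric submatrix
#' restricted to its support has rank `|support| - 1`, i.e. the support
#' fixes the flux distribution up to scale. The zero vector is not
#' elementary.
#'
#' @inheritParams is_steady_state
#' @param tol relative tolerance for support membership.
#' @export
is_elementary <- function(v, net, tol = 1e-9) {
  if (inherits(v, "flux_mode")) v <- v$v
  N <- stoich_matrix(net)
  x <- stats::setNames(numeric(ncol(N)), colnames(N))
  x[intersect(names(v), names(x))] <- v[intersect(names(v), names(x))]
  scale <- max(abs(x))
  if (scale == 0) return(FALSE)
  supp <- which(abs(x) > tol * scale)
  mat_rank(N[, supp, drop = FALSE]) == length(supp) - 1L
}

#' Exhaustively enumerate Elementary Flux Modes (toy scale)
#'
#' Double Description enumeration of the extreme rays of the flux cone
#' `{v : N v = 0, v >= 0}` after reversible splitting: starting from the
#' nonnegative orthant, each steady-state balance is intersected in turn,
#' keeping zero-set-adjacent ray pairs only. Spurious two-cycles from the
#' splitting are removed and reversible-support modes are reported once,
#' in a canonical orientation.
#'
#' The tableau grows combinatorially with network size, so this routine
#' guards against networks with more than `max_cols` columns after
#' splitting; larger networks should go through the constrained sampler.
#'
#' @param net a [metabolic_network()].
#' @param max_cols refusal guard on split-network columns.
#' @return list of [flux_mode()] on `net`, normalized to unit maximum
#'   absolute flux, each verified by the rank test.
#' @export
enumerate_efms_exhaustive <- function(net, max_cols = 32L) {
  sp <- split_reversibles(net)
  N <- stoich_matrix(sp$network)
  n <- ncol(N)
  if (n > max_cols) {
    stop("network has ", n, " columns after splitting (guard ", max_cols,
         "); use sample_constrained_efms() for larger networks")
  }
  R <- diag(n)
  if (nrow(N) > 0) {
    # fewer nonzeros first keeps intermediate tableaus small
    for (i in order(rowSums(N != 0))) {
      R <- dd_step(R, N[i, ])
      if (!nrow(R)) break
    }
  }
  collect_split_rays(R, net, sp)
}

# One double-description step: intersect the cone spanned by rays (rows of
# R) with the hyperplane {a v = 0}, using the combinatorial adjacency test.
dd_step <- function(R, a, tol = 1e-9) {
  if (!nrow(R)) return(R)
  s <- as.vector(R %*% a)
  s[abs(s) <= tol] <- 0
  zero <- which(s == 0)
  pos <- which(s > 0)
  neg <- which(s < 0)
  out <- R[zero, , drop = FALSE]
  if (!length(pos) || !length(neg)) return(out)
  Z <- R == 0  # zero sets (rays are normalized, entries exactly 0 kept exact)
  new_rows <- list()
  for (p in pos) {
    zp <- Z[p, ]
    for (m in neg) {
      z <- zp & Z[m, ]
      # adjacency: no third ray's zero set contains Z(p) & Z(m)
      others <- setdiff(seq_len(nrow(R)), c(p, m))
      if (length(others)) {
        cover <- Z[others, z, drop = FALSE]
        if (any(rowSums(cover) == sum(z))) next
      }
      r <- s[p] * R[m, ] - s[m] * R[p, ]
      r[abs(r) <= tol * max(abs(r))] <- 0
      new_rows[[length(new_rows) + 1L]] <- r / max(abs(r))
    }
  }
  if (length(new_rows)) out <- rbind(out, do.call(rbind, new_rows))
  out
}

# Map split-network rays back to the original network: drop two-cycles,
# canonicalize orientation, deduplicate, verify.
collect_split_rays <- function(R, net, sp, tol = 1e-9) {
  if (!nrow(R)) return(list())
  colnames(R) <- reaction_ids(sp$network)
  pairs <- sp$pairs
  modes <- list()
  seen <- character()
  for (i in seq_len(nrow(R))) {
    ray <- R[i, ]
    ray[abs(ray) <= tol * max(abs(ray))] <- 0
    if (nrow(pairs)) {
      both <- ray[pairs$fwd] > 0 & ray[pairs$bwd] > 0
      if (any(both)) next  # spurious two-cycle (alone or embedded)
    }
    v <- unsplit_flux(ray, net, pairs)
    if (max(abs(v)) == 0) next
    v <- normalize_flux(v)
    # canonical orientation: first nonzero entry positive when the mirror
    # image is also a valid mode (fully reversible support)
    nz <- which(abs(v) > tol)
    reversible <- vapply(net$reactions[nz], `[[`, NA, "reversible")
    if (all(reversible) && v[nz[1L]] < 0) v <- -v
    key <- paste(names(v)[nz], sign(v[nz]), collapse = ";")
    if (key %in% seen) next
    seen <- c(seen, key)
    mode <- flux_mode(v, net)
    mode$verified_elementary <- is_elementary(mode, net)
    modes[[length(modes) + 1L]] <- mode
  }
  # deterministic order: support size, then support signature
  ord <- order(vapply(modes, function(m) length(m$support), 0L),
               vapply(modes, function(m) paste(m$support, collapse = ";"), ""))
  modes[ord]
}

#' Brute-force EFM enumeration (independent oracle)
#'
#' Enumerates support subsets of the split network in increasing size and
#' keeps those whose stoichiometric submatrix has a one-dimensional kernel
#' spanned by a strictly nonzero, sign-consistent vector — exactly the
#' elementary supports. Subsets containing both halves of a split pair or a
#' previously accepted support are pruned. Exponential in the number of
#' columns, intended purely as a small-scale oracle.
#'
#' @param net a [metabolic_network()].
#' @param max_cols refusal guard on split-network columns.
#' @return list of [flux_mode()], same conventions as
#'   [enumerate_efms_exhaustive()].
#' @export
brute_force_efms <- function(net, max_cols = 18L) {
  sp <- split_reversibles(net)
  N <- stoich_matrix(sp$network)
  n <- ncol(N)
  if (n > max_cols) {
    stop("network has ", n, " columns after splitting (guard ", max_cols, ")")
  }
  rids <- colnames(N)
  pair_idx <- if (nrow(sp$pairs)) {
    cbind(match(sp$pairs$fwd, rids), match(sp$pairs$bwd, rids))
  } else matrix(0L, 0, 2)
  accepted <- list()
  supports <- list()
  for (k in seq_len(n)) {
    sets <- utils::combn(n, k)
    for (ci in seq_len(ncol(sets))) {
      S <- sets[, ci]
      if (nrow(pair_idx) &&
          any(pair_idx[, 1] %in% S & pair_idx[, 2] %in% S)) next
      skip <- FALSE
      for (acc in supports) {
        if (all(acc %in% S)) { skip <- TRUE; break }
      }
      if (skip) next
      K <- null_space(N[, S, drop = FALSE])
      if (ncol(K) != 1L) next
      w <- K[, 1L]
      if (any(abs(w) < 1e-9 * max(abs(w)))) next  # support smaller than S
      if (any(w > 0) && any(w < 0)) next          # sign-infeasible
      if (sum(w) < 0) w <- -w
      v <- stats::setNames(numeric(n), rids)
      v[S] <- w
      supports[[length(supports) + 1L]] <- S
      accepted[[length(accepted) + 1L]] <- v
    }
  }
  if (!length(accepted)) return(list())
  collect_split_rays(do.call(rbind, accepted), net, sp)
}

#' Write flux modes as a CSV matrix (modes x reactions)
#'
#' @param modes list of [flux_mode()].
#' @param path output path.
#' @export
write_efm_csv <- function(modes, path) {
  if (!length(modes)) stop("no modes to write")
  M <- do.call(rbind, lapply(modes, function(m) m$v))
  rownames(M) <- seq_len(nrow(M))
  utils::write.csv(as.data.frame(M), path, row.names = FALSE)
  invisible(path)
}

#' Read flux modes from a CSV matrix (modes x reactions)
#'
#' Column names are reaction ids, optionally translated through `aliases`;
#' modes are renormalized to unit maximum absolute flux on load, since the
#' scale convention of an external file is unknown and all scores downstream
#' are scale-invariant.
#'
#' @param path CSV path, rows = modes, header of reaction ids.
#' @param net network the modes live on.
#' @param aliases optional named character vector, column name -> reaction id.
#' @export
read_efm_csv <- function(path, net, aliases = NULL) {
  M <- utils::read.csv(path, check.names = FALSE)
  cn <- colnames(M)
  if (!is.null(aliases)) {
    hit <- cn %in% names(aliases)
    cn[hit] <- aliases[cn[hit]]
    colnames(M) <- cn
  }
  unknown <- setdiff(cn, reaction_ids(net))
  if (length(unknown)) {
    stop("unknown reaction column(s): ", paste(unknown, collapse = ", "))
  }
  lapply(seq_len(nrow(M)), function(i) {
    flux_mode(normalize_flux(unlist(M[i, ])), net)
  })
}
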