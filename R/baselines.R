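#' Parsimonious flux balance analysis under the analysis constraints
#'
#' Two-stage linear programming on the reversibility-split network. Stage 1
#' maximizes the sum of the production fluxes of the `objective` reactions
#' (by default biomass, collagen assembly and stroma recruitment) subject to
#' the steady state, the hard/forbidden/linear constraints of `cs` (the
#' support cap is not applied: parsimony here is flux parsimony, not support
#' cardinality) and `0 <= v <= flux_bound` on every split flux. Stage 2
#' fixes the attained objective and minimizes the total (split) flux,
#' returning the parsimonious optimum.
#'
#' Strict constraints are relaxed to a margin of `eps` inside the LPs.
#'
#' @param net a [metabolic_network()].
#' @param cs a [constraint_set()].
#' @param flux_bound upper bound applied to every split flux.
#' @param objective reaction ids whose summed net flux is maximized.
#' @param eps margin replacing strictness.
#' @param backend `"simplex"` or `"quadprog"` (two independent solvers).
#' @return object of class `lp_solution`: `fluxes` (net, on `net`'s
#'   reactions), `objective_value` (stage-1 optimum), `total_flux`
#'   (stage-2 sum of split fluxes), `status`.
#' @export
pfba <- function(net, cs, flux_bound = 15, objective = c("BM", "COLLAG", "STROMA"),
                 eps = 1e-6, backend = c("simplex", "quadprog")) {
  backend <- match.arg(backend)
  stopifnot(flux_bound > 0)
  missing_obj <- setdiff(objective, reaction_ids(net))
  if (length(missing_obj)) {
    stop("objective reaction(s) not in network: ",
         paste(missing_obj, collapse = ", "))
  }
  cs_nosize <- cs
  cs_nosize$max_support <- Inf
  P <- build_polytope(net, cs_nosize, eps_act = eps)
  # replace the ray normalization by the flux box of the FBA formulation
  n <- P$n
  A_eq <- P$A_eq[-nrow(P$A_eq), , drop = FALSE]
  b_eq <- P$b_eq[-length(P$b_eq)]
  ub <- ifelse(P$ub > 0, flux_bound, 0)
  obj <- numeric(n)
  for (r in objective) {
    obj[match(r, P$rids)] <- 1
    jb <- match(paste0(r, "_rev"), P$rids)
    if (!is.na(jb)) obj[jb] <- -1
  }
  s1 <- solve_lp(obj, A_eq = A_eq, b_eq = b_eq, A_ge = P$A_ge, b_ge = P$b_ge,
                 lb = 0, ub = ub, maximize = TRUE, backend = backend)
  if (s1$status != "optimal") {
    return(structure(list(fluxes = NULL, objective_value = NA_real_,
                          total_flux = NA_real_, status = s1$status),
                     class = "lp_solution"))
  }
  opt <- s1$objective
  A_ge2 <- rbind(P$A_ge, obj)
  b_ge2 <- c(P$b_ge, opt - 1e-8 * max(1, abs(opt)))
  s2 <- solve_lp(rep(1, n), A_eq = A_eq, b_eq = b_eq, A_ge = A_ge2,
                 b_ge = b_ge2, lb = 0, ub = ub, maximize = FALSE,
                 backend = backend)
  sol <- if (s2$status == "optimal") s2 else s1
  v_split <- stats::setNames(sol$x, P$rids)
  structure(list(
    fluxes = unsplit_flux(v_split, net, P$split$pairs),
    objective_value = opt,
    total_flux = sum(sol$x),
    status = "optimal"
  ), class = "lp_solution")
}

#' @export
print.lp_solution <- function(x, ...) {
  cat("lp_solution:", x$status)
  if (identical(x$status, "optimal")) {
    cat(sprintf(", objective %.6g, total flux %.6g", x$objective_value,
                x$total_flux))
  }
  cat("\n")
  invisible(x)
}

#' Reaction essentiality under a constraint set
#'
#' TRUE when forcing the reaction's flux to zero (both directions) makes
#' the constrained steady-state polytope infeasible.
#'
#' @inheritParams pfba
#' @param rxn reaction id to knock out.
#' @export
is_essential <- function(net, cs, rxn, flux_bound = 15, eps = 1e-6) {
  cs_nosize <- cs
  cs_nosize$max_support <- Inf
  P <- build_polytope(net, cs_nosize, eps_act = eps)
  n <- P$n
  A_eq <- P$A_eq[-nrow(P$A_eq), , drop = FALSE]
  b_eq <- P$b_eq[-length(P$b_eq)]
  ub <- ifelse(P$ub > 0, flux_bound, 0)
  ko <- match(rxn, P$rids)
  if (is.na(ko)) stop("no reaction with id ", rxn)
  ub[ko] <- 0
  jb <- match(paste0(rxn, "_rev"), P$rids)
  if (!is.na(jb)) ub[jb] <- 0
  sol <- solve_lp(rep(1, n), A_eq = A_eq, b_eq = b_eq, A_ge = P$A_ge,
                  b_ge = P$b_ge, lb = 0, ub = ub)
  sol$status == "infeasible"
}

#' Hit-and-run flux sampling of the constrained polytope
#'
#' Samples the polytope `{v : N v = 0, hard directions >= eps, forbidden
#' directions = 0, linear constraints with margin eps, 0 <= v <=
#' flux_bound}` on the split network with an artificial-centering
#' hit-and-run walk in nullspace coordinates: directions are drawn towards
#' previously visited points relative to the running sample mean (random
#' directions during warm-up), and the chain is thinned to `n` kept
#' samples. Reproducible from `seed`.
#'
#' @inheritParams pfba
#' @param n number of samples to return.
#' @param seed integer seed.
#' @param warmup number of warm-up steps.
#' @param chain_factor target total chain length as a multiple of `n`.
#' @param max_chain hard cap on the chain length.
#' @return numeric matrix `n x reactions(net)` of net steady-state fluxes.
#' @export
flux_sample <- function(net, cs, n = 1000L, seed = 1L, flux_bound = 15,
                        eps = 1e-6, warmup = 1000L, chain_factor = 100L,
                        max_chain = 1000000L) {
  cs_nosize <- cs
  cs_nosize$max_support <- Inf
  P <- build_polytope(net, cs_nosize, eps_act = eps)
  A_eq <- P$A_eq[-nrow(P$A_eq), , drop = FALSE]
  ub <- ifelse(P$ub > 0, flux_bound, 0)
  # fixed-zero columns are removed from the walk entirely
  keep <- which(ub > 0)
  Nk <- A_eq[, keep, drop = FALSE]
  B <- null_space(Nk)
  if (ncol(B) == 0L) stop("constrained polytope has empty interior")
  # inequality system G u <= h around a feasible point v0
  G_v <- rbind(-diag(length(keep)), diag(length(keep)))
  h_v <- c(rep(0, length(keep)), rep(flux_bound, length(keep)))
  if (!is.null(P$A_ge)) {
    G_v <- rbind(G_v, -P$A_ge[, keep, drop = FALSE])
    h_v <- c(h_v, -P$b_ge)
  }
  # feasible starting point: average a few LP vertices of the polytope
  verts <- list()
  for (k in 1:4) {
    objk <- sin(seq_len(length(keep)) * k * 0.7) + 1.5
    s <- solve_lp(objk, A_eq = Nk, b_eq = rep(0, nrow(Nk)),
                  A_ge = if (is.null(P$A_ge)) NULL else P$A_ge[, keep, drop = FALSE],
                  b_ge = P$b_ge, lb = 0, ub = rep(flux_bound, length(keep)),
                  maximize = (k %% 2 == 0))
    if (s$status == "optimal") verts[[length(verts) + 1L]] <- s$x
  }
  if (!length(verts)) {
    stop("constrained polytope is empty: no feasible point found (check the ",
         "hard and linear constraints)")
  }
  v0 <- Reduce(`+`, verts) / length(verts)
  G <- G_v %*% B
  slack0 <- h_v - as.vector(G_v %*% v0)
  chain_len <- min(max_chain, max(chain_factor * n, n))
  thin <- max(1L, floor(chain_len / n))
  d_dim <- ncol(B)
  samples <- matrix(0, n, length(keep))
  with_seed(seed, {
    u <- numeric(d_dim)
    center <- u
    visited <- matrix(0, 0, d_dim)
    kept <- 0L
    step <- 0L
    while (kept < n) {
      step <- step + 1L
      if (step > warmup && nrow(visited) >= 2L) {
        ref <- visited[sample.int(nrow(visited), 1L), ]
        d <- ref - center
        if (sqrt(sum(d^2)) < 1e-12) d <- stats::rnorm(d_dim)
      } else {
        d <- stats::rnorm(d_dim)
      }
      d <- d / sqrt(sum(d^2))
      a <- as.vector(G %*% d)
      slack <- slack0 - as.vector(G %*% u)
      pos <- a > 1e-12
      neg <- a < -1e-12
      tmax <- if (any(pos)) min(slack[pos] / a[pos]) else Inf
      tmin <- if (any(neg)) max(slack[neg] / a[neg]) else -Inf
      if (!is.finite(tmax) || !is.finite(tmin) || tmax <= tmin) next
      u <- u + stats::runif(1, tmin, tmax) * d
      if (nrow(visited) < 200L) {
        visited <- rbind(visited, u)
      } else {
        visited[sample.int(200L, 1L), ] <- u
      }
      center <- center + (u - center) / step
      if (step > warmup && step %% thin == 0L) {
        kept <- kept + 1L
        samples[kept, ] <- v0[seq_len(length(keep))] + as.vector(B %*% u)
      }
    }
  })
  out <- matrix(0, n, P$n, dimnames = list(NULL, P$rids))
  out[, keep] <- samples
  # map split fluxes back to net fluxes on the original reactions
  res <- matrix(0, n, length(net$reactions),
                dimnames = list(NULL, reaction_ids(net)))
  for (j in seq_along(net$reactions)) {
    rid <- reaction_ids(net)[j]
    res[, j] <- out[, rid]
    rb <- paste0(rid, "_rev")
    if (rb %in% colnames(out)) res[, j] <- res[, j] - out[, rb]
  }
  res
}
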