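#' Constraint set for constrained EFM computation
#'
#' Encodes the four constraint classes used to select biologically relevant
#' flux modes:
#' \itemize{
#' \item hard activity constraints — a directed reaction flux must be
#'   strictly positive (e.g. glucose must be consumed);
#' \item forbidden directions — flux into a direction must be zero, while
#'   zero total flux stays allowed (the "desired observation" encoding);
#' \item strict linear inequalities `v[greater] > v[lesser]` (e.g. collagen
#'   production above biomass production);
#' \item a support-size cap: the number of active reactions must stay
#'   strictly below `max_support`.
#' }
#'
#' Directions refer to the orientation in which a reaction is written:
#' `"fwd"` is positive flux, `"bwd"` negative.
#'
#' @param hard_active data frame with columns `rxn`, `dir` (`"fwd"`/`"bwd"`).
#' @param forbidden_direction same layout as `hard_active`.
#' @param linear data frame with columns `greater`, `lesser` (reaction ids).
#' @param max_support integer cap (strict), or `Inf` for no cap.
#' @export
constraint_set <- function(hard_active = directed(), forbidden_direction = directed(),
                           linear = data.frame(greater = character(),
                                               lesser = character()),
                           max_support = Inf) {
  stopifnot(all(hard_active$dir %in% c("fwd", "bwd")),
            all(forbidden_direction$dir %in% c("fwd", "bwd")))
  key <- function(d) paste(d$rxn, d$dir)
  clash <- intersect(key(hard_active), key(forbidden_direction))
  if (length(clash)) {
    stop("direction(s) both required and forbidden: ",
         paste(clash, collapse = ", "))
  }
  structure(list(hard_active = hard_active,
                 forbidden_direction = forbidden_direction,
                 linear = linear, max_support = max_support),
            class = "constraint_set")
}

# linear-constraint data frames may omit the coefficient columns, in which
# case the comparison is the plain v[greater] > v[lesser]
normalize_linear <- function(lin) {
  if (is.null(lin$greater_coef)) lin$greater_coef <- rep(1, nrow(lin))
  if (is.null(lin$lesser_coef)) lin$lesser_coef <- rep(1, nrow(lin))
  lin
}

#' Directed reaction reference helper
#' @param rxn reaction ids; @param dir directions, recycled.
#' @export
directed <- function(rxn = character(), dir = character()) {
  if (length(rxn) && length(dir) == 1L) dir <- rep(dir, length(rxn))
  data.frame(rxn = rxn, dir = dir, stringsAsFactors = FALSE)
}

#' @export
print.constraint_set <- function(x, ...) {
  cat("constraint_set:", nrow(x$hard_active), "hard,",
      nrow(x$forbidden_direction), "forbidden directions,",
      nrow(x$linear), "linear, support cap", x$max_support, "\n")
  invisible(x)
}

#' Locate a metabolite's exchange reaction and its flux directions
#'
#' Resolves the (possibly subset-merged) exchange reaction for a metabolite
#' through its boundary species: the direction that consumes the boundary
#' species is uptake. Works on compressed networks, where the returned
#' `coef` is the boundary-species coefficient that converts the reaction's
#' flux into an exchange rate in original units.
#'
#' @param net a [metabolic_network()].
#' @param met metabolite id (boundary or internal).
#' @return list with `rxn`, `coef`, `uptake` and `secretion` (directions,
#'   `"fwd"`/`"bwd"`).
#' @export
uptake_direction <- function(net, met) {
  i <- match(met, net$metabolites$id)
  if (is.na(i)) stop("no metabolite with id ", met)
  if (!net$metabolites$boundary[i]) {
    rid <- exchange_for_metabolite(net, met)
    r <- reaction_by_id(net, rid)
    c_bnd <- -r$stoich[[met]]  # internal production mirrors boundary use
  } else {
    bt <- boundary_touchers(net, met)
    if (!length(bt$rxn)) stop("no exchange reaction for metabolite ", met)
    if (length(bt$rxn) > 1L) {
      stop("ambiguous exchange for metabolite ", met, ": ",
           paste(bt$rxn, collapse = ", "))
    }
    rid <- bt$rxn
    c_bnd <- bt$coef
  }
  list(rxn = rid, coef = c_bnd,
       uptake = if (c_bnd < 0) "fwd" else "bwd",
       secretion = if (c_bnd < 0) "bwd" else "fwd")
}

#' Default constraint set from an exometabolomics table
#'
#' Builds the analysis constraint set: hard activity for glucose uptake,
#' lactate secretion, glutamine uptake and biomass production (the three
#' followed cell functions — proliferation, collagen formation, stroma
#' response — must all carry flux; the latter two follow from the strict
#' linear constraints once biomass is active); for every other measured
#' metabolite with a directional sign, the opposite exchange direction is
#' forbidden ("-" forbids secretion, "+" forbids uptake, "+/-" leaves the
#' exchange free); strict linear constraints requiring collagen and stroma
#' production above biomass production; and a support cap of 60 active
#' reactions.
#'
#' @param net network carrying the exchange reactions.
#' @param table an exometabolomics table, see [table1_constants()].
#' @param aliases metabolite-name to model-id mapping.
#' @param max_support strict support cap.
#' @export
default_constraint_set <- function(net, table = table1_constants(),
                                   aliases = default_exchange_aliases(),
                                   max_support = 60L) {
  # flux is demanded in all three followed cell functions: proliferation,
  # collagen formation and stroma response (collagen and stroma activity
  # follow from the strict linear constraints once biomass is active)
  db0 <- uptake_direction(net, aliases[["biomass"]])
  hard <- directed(db0$rxn, db0$secretion)
  forb <- NULL
  for (i in seq_len(nrow(table))) {
    met_key <- table$metabolite[i]
    if (!met_key %in% names(aliases)) {
      stop("no model alias for metabolite ", met_key)
    }
    d <- uptake_direction(net, aliases[[met_key]])
    if (table$constraint_type[i] == "hard") {
      want <- if (table$sign[i] == "-") d$uptake else d$secretion
      hard <- rbind(hard, directed(d$rxn, want))
    } else if (table$sign[i] == "-") {
      forb <- rbind(forb, directed(d$rxn, d$secretion))
    } else if (table$sign[i] == "+") {
      forb <- rbind(forb, directed(d$rxn, d$uptake))
    }
  }
  dc <- uptake_direction(net, aliases[["collagen"]])
  ds <- uptake_direction(net, aliases[["stroma"]])
  db <- uptake_direction(net, aliases[["biomass"]])
  # compare secretion rates: coefficient-weighted so the comparison stays in
  # original flux units on compressed networks where exchanges sit inside
  # ratio-scaled enzyme subsets
  lin <- data.frame(
    greater = c(dc$rxn, ds$rxn), greater_coef = c(dc$coef, ds$coef),
    lesser = db$rxn, lesser_coef = db$coef,
    stringsAsFactors = FALSE
  )
  constraint_set(hard_active = hard, forbidden_direction = forb,
                 linear = lin, max_support = max_support)
}

#' Check a flux mode against a constraint set
#'
#' The mode is normalized to unit maximum absolute flux before checking, so
#' `eps` is a relative margin. Strict constraints hold with margin `> eps`;
#' forbidden directions tolerate fluxes up to `eps`.
#'
#' @param mode a [flux_mode()] or named flux vector.
#' @param cs a [constraint_set()].
#' @param eps relative margin.
#' @return list with `ok` (flag) and `violations` (character labels:
#'   `"hard:<rxn>"`, `"forbidden:<rxn>"`, `"linear:<a>><b>"`, `"size"`).
#' @export
satisfies <- function(mode, cs, eps = 1e-6) {
  v <- if (inherits(mode, "flux_mode")) mode$v else mode
  v <- normalize_flux(v)
  val <- function(r) if (r %in% names(v)) v[[r]] else 0
  viol <- character()
  for (i in seq_len(nrow(cs$hard_active))) {
    r <- cs$hard_active$rxn[i]
    f <- val(r) * (if (cs$hard_active$dir[i] == "fwd") 1 else -1)
    if (!(f > eps)) viol <- c(viol, paste0("hard:", r))
  }
  for (i in seq_len(nrow(cs$forbidden_direction))) {
    r <- cs$forbidden_direction$rxn[i]
    f <- val(r) * (if (cs$forbidden_direction$dir[i] == "fwd") 1 else -1)
    if (f > eps) viol <- c(viol, paste0("forbidden:", r))
  }
  lin <- normalize_linear(cs$linear)
  for (i in seq_len(nrow(lin))) {
    g <- lin$greater[i]
    l <- lin$lesser[i]
    lhs <- val(g) * lin$greater_coef[i] - val(l) * lin$lesser_coef[i]
    if (!(lhs > eps)) viol <- c(viol, paste0("linear:", g, ">", l))
  }
  supp <- sum(abs(v) > eps)
  if (!(supp < cs$max_support)) viol <- c(viol, "size")
  list(ok = !length(viol), violations = viol)
}

# --- constrained sampler ----------------------------------------------------

# polytope of the constrained flux cone, on the split network, with the
# normalization sum(v) = 1 (flux modes are rays; the normalization picks one
# representative per ray and bounds the polytope)
build_polytope <- function(net, cs, eps_act = 1e-4) {
  sp <- split_reversibles(net)
  N <- stoich_matrix(sp$network)
  rids <- colnames(N)
  n <- ncol(N)
  col_of <- function(rxn, dir) {
    if (dir == "fwd") {
      j <- match(rxn, rids)
      if (is.na(j)) stop("no forward column for ", rxn)
    } else {
      j <- match(paste0(rxn, "_rev"), rids)
      if (is.na(j)) j <- NA_integer_  # irreversible: backward absent
    }
    j
  }
  ub <- rep(1, n)
  for (i in seq_len(nrow(cs$forbidden_direction))) {
    j <- col_of(cs$forbidden_direction$rxn[i], cs$forbidden_direction$dir[i])
    if (!is.na(j)) ub[j] <- 0
  }
  A_eq <- rbind(N, rep(1, n))
  b_eq <- c(rep(0, nrow(N)), 1)
  A_ge <- NULL
  b_ge <- NULL
  ge_kind <- character()
  for (i in seq_len(nrow(cs$hard_active))) {
    j <- col_of(cs$hard_active$rxn[i], cs$hard_active$dir[i])
    if (is.na(j)) stop("hard constraint on missing direction: ",
                       cs$hard_active$rxn[i])
    a <- numeric(n)
    a[j] <- 1
    A_ge <- rbind(A_ge, a)
    b_ge <- c(b_ge, eps_act)
    ge_kind <- c(ge_kind, "hard")
  }
  net_row <- function(rxn, sgn) {
    a <- numeric(n)
    a[col_of(rxn, "fwd")] <- sgn
    jb <- col_of(rxn, "bwd")
    if (!is.na(jb)) a[jb] <- -sgn
    a
  }
  lin <- normalize_linear(cs$linear)
  for (i in seq_len(nrow(lin))) {
    a <- net_row(lin$greater[i], lin$greater_coef[i]) +
      net_row(lin$lesser[i], -lin$lesser_coef[i])
    A_ge <- rbind(A_ge, a)
    b_ge <- c(b_ge, eps_act)
    ge_kind <- c(ge_kind, "linear")
  }
  list(split = sp, N = N, rids = rids, n = n, ub = ub,
       A_eq = A_eq, b_eq = b_eq, A_ge = A_ge, b_ge = b_ge, ge_kind = ge_kind)
}

# solve an LP over the polytope restricted to the columns in `cols`
# (all other fluxes structurally zero); returns x in full coordinates
polytope_lp <- function(P, obj = NULL, cols = NULL, force_active = NULL,
                        eps_act = 1e-4, backend = "simplex") {
  if (is.null(cols)) cols <- which(P$ub > 0)
  cols <- sort(cols)
  infeas <- list(status = "infeasible", x = rep(NA_real_, P$n),
                 objective = NA_real_)
  # a hard-activity or forced column outside the support is a contradiction
  act_rows <- which(P$ge_kind == "hard")
  for (i in act_rows) {
    j <- which(P$A_ge[i, ] > 0)
    if (!all(j %in% cols)) return(infeas)
  }
  if (!is.null(force_active) && !all(force_active %in% cols)) return(infeas)
  A_ge <- P$A_ge[, cols, drop = FALSE]
  b_ge <- P$b_ge
  if (!is.null(force_active)) {
    for (j in force_active) {
      a <- numeric(length(cols))
      a[match(j, cols)] <- 1
      A_ge <- rbind(A_ge, a)
      b_ge <- c(b_ge, eps_act)
    }
  }
  if (is.null(obj)) obj <- rep(1, P$n)
  sol <- solve_lp(obj[cols], A_eq = P$A_eq[, cols, drop = FALSE],
                  b_eq = P$b_eq, A_ge = A_ge, b_ge = b_ge,
                  lb = 0, ub = P$ub[cols], backend = backend)
  if (sol$status != "optimal") {
    # cross-check with the quadratic backend before declaring failure
    if (backend == "simplex") {
      sol <- solve_lp(obj[cols], A_eq = P$A_eq[, cols, drop = FALSE],
                      b_eq = P$b_eq, A_ge = A_ge, b_ge = b_ge,
                      lb = 0, ub = P$ub[cols], backend = "quadprog")
    }
    if (sol$status != "optimal") {
      return(list(status = sol$status, x = rep(NA_real_, P$n),
                  objective = NA_real_))
    }
  }
  x <- numeric(P$n)
  x[cols] <- sol$x
  list(status = "optimal", x = x, objective = sol$objective)
}

#' Sample Elementary Flux Modes under a constraint set
#'
#' Computes distinct EFMs of `net` that satisfy all constraints in `cs`.
#' Small networks (at most `enum_max_cols` columns after reversible
#' splitting) are enumerated exhaustively and filtered, which is exact and
#' complete. Larger networks are sampled: each round solves a linear program
#' with a seeded random objective over the constrained, normalized flux
#' polytope; the vertex found has a small support, inside which all
#' elementary supports are enumerated by double description and checked
#' against the constraints and the elementarity rank test. Visited vertex
#' supports are cached so no round is repeated. Repeated calls with
#' different seeds extend the sample.
#'
#' @param net a [metabolic_network()] (typically compressed).
#' @param cs a [constraint_set()].
#' @param n maximum number of modes to return.
#' @param seed integer seed for the randomized search.
#' @param time_limit wall-clock budget in seconds (sampling path only).
#' @param eps relative margin for [satisfies()].
#' @param eps_act activation threshold inside the LPs, on the normalized
#'   (`sum v = 1`) scale.
#' @param enum_max_cols threshold below which exhaustive enumeration is used.
#' @param stall_rounds stop after this many consecutive unproductive rounds.
#' @return list of [flux_mode()], each satisfying `cs` and verified
#'   elementary; empty (with attribute `infeasible = TRUE`) when the
#'   constraint set is infeasible on `net`.
#' @export
sample_constrained_efms <- function(net, cs, n = 100L, seed = 1L,
                                    time_limit = Inf, eps = 1e-6,
                                    eps_act = 1e-4, enum_max_cols = 24L,
                                    stall_rounds = 150L) {
  sp_cols <- ncol(stoich_matrix(split_reversibles(net)$network))
  if (sp_cols <= enum_max_cols) {
    all_modes <- enumerate_efms_exhaustive(net, max_cols = enum_max_cols)
    keep <- vapply(all_modes, function(m) satisfies(m, cs, eps)$ok, NA)
    modes <- utils::head(all_modes[keep], n)
    if (!length(modes)) attr(modes, "infeasible") <- TRUE
    return(modes)
  }
  P <- build_polytope(net, cs, eps_act = eps_act)
  feas <- polytope_lp(P, eps_act = eps_act)
  if (feas$status != "infeasible" && feas$status != "optimal") {
    feas <- polytope_lp(P, eps_act = eps_act, backend = "quadprog")
  }
  if (feas$status == "infeasible") {
    out <- list()
    attr(out, "infeasible") <- TRUE
    return(out)
  }
  modes <- list()
  near_seeds <- list()      # supports of rays that narrowly miss the cs
  seen_support <- character()
  seen_mode <- character()
  seen_near <- character()
  free_cols <- which(P$ub > 0)
  mode_cols <- function(m) {
    which(P$rids %in% c(m$support, paste0(m$support, "_rev")) & P$ub > 0)
  }
  t0 <- Sys.time()
  with_seed(seed, {
    stall <- 0L
    round_i <- 0L
    while (length(modes) < n && stall < stall_rounds) {
      round_i <- round_i + 1L
      if (as.numeric(Sys.time() - t0, units = "secs") > time_limit) {
        attr(modes, "incomplete") <- TRUE
        break
      }
      n_seeds <- length(modes) + length(near_seeds)
      if (n_seeds && stats::runif(1) < 0.7) {
        # neighborhood round: enumerate the sub-cone spanned by a found
        # mode or a near-miss ray support, with part of the base dropped
        # (forcing genuine pathway swaps) and a few random directions added
        if (length(modes) >= 2L && stats::runif(1) < 0.2) {
          picks <- sample(length(modes), 2L)
          base <- union(mode_cols(modes[[picks[1L]]]),
                        mode_cols(modes[[picks[2L]]]))
          n_extra <- 3L
        } else {
          pick <- sample(n_seeds, 1L)
          base <- if (pick <= length(modes)) mode_cols(modes[[pick]]) else
            near_seeds[[pick - length(modes)]]
          n_drop <- sample(0:3, 1L)
          if (n_drop && length(base) > n_drop) {
            base <- setdiff(base, sample(base, n_drop))
          }
          n_extra <- sample(4:10, 1L)
        }
        pool <- setdiff(free_cols, base)
        S <- sort(c(base, sample(pool, min(n_extra, length(pool)))))
      } else {
        # vertex round: a seeded mixed-sign objective visits a vertex on
        # a random face of the constrained polytope; forcing a random
        # direction active spreads the search over the cone
        obj <- stats::runif(P$n, -1, 1)
        force <- NULL
        if (round_i > 1L && stats::runif(1) < 0.7) {
          unseen <- free_cols[!(P$rids[free_cols] %in%
                                  unlist(lapply(modes, `[[`, "support")))]
          pool <- if (length(unseen) && stats::runif(1) < 0.5) unseen else free_cols
          if (length(pool)) force <- sample(pool, 1L)
        }
        sol <- polytope_lp(P, obj = obj, force_active = force,
                           eps_act = eps_act)
        if (sol$status != "optimal") {
          if (is.null(force)) stall <- stall + 1L
          next
        }
        S <- which(sol$x > 1e-9)
      }
      key <- paste(S, collapse = ",")
      if (key %in% seen_support) { stall <- stall + 1L; next }
      seen_support <- c(seen_support, key)
      # all elementary supports within the candidate column set: the
      # restricted cone has a low-dimensional kernel, so double
      # description enumeration is cheap
      res <- vertex_cone_modes(P, S, net, cs, eps)
      found <- 0L
      for (mode in res$modes) {
        mkey <- paste(mode$support, collapse = ";")
        if (mkey %in% seen_mode) next
        seen_mode <- c(seen_mode, mkey)
        modes[[length(modes) + 1L]] <- mode
        found <- found + 1L
        if (length(modes) >= n) break
      }
      for (nm in res$near) {
        nkey <- paste(nm, collapse = ",")
        if (nkey %in% seen_near) next
        seen_near <- c(seen_near, nkey)
        near_seeds[[length(near_seeds) + 1L]] <- nm
      }
      if (length(near_seeds) > 200L) {
        near_seeds <- near_seeds[seq(length(near_seeds) - 199L,
                                     length(near_seeds))]
      }
      stall <- if (found) 0L else stall + 1L
    }
  })
  modes
}

# enumerate the elementary rays whose support lies within the column set S
# (double description on the restricted columns); classify each against the
# constraint set. Returns satisfying modes plus the supports of near-miss
# rays (few violations), which make good seeds for further search.
vertex_cone_modes <- function(P, S, net, cs, eps, max_dim = 10L,
                              max_rays = 2000L, near_max_viol = 2L) {
  empty <- list(modes = list(), near = list())
  NS <- P$N[, S, drop = FALSE]
  NS <- NS[rowSums(NS != 0) > 0, , drop = FALSE]
  # guard: give up on sub-cones whose enumeration could blow up
  if (length(S) - mat_rank(NS) > max_dim) return(empty)
  R <- diag(length(S))
  if (nrow(NS)) {
    for (i in order(rowSums(NS != 0))) {
      R <- dd_step(R, NS[i, ])
      if (!nrow(R)) break
      if (nrow(R) > max_rays) return(empty)
    }
  }
  out <- empty
  if (!nrow(R)) return(out)
  tc <- if (nrow(P$split$pairs)) {
    cbind(match(P$split$pairs$fwd, P$rids), match(P$split$pairs$bwd, P$rids))
  } else matrix(0L, 0, 2)
  for (i in seq_len(nrow(R))) {
    w <- R[i, ]
    supp <- S[w > 1e-9]
    if (!length(supp)) next
    if (nrow(tc) && any(tc[, 1] %in% supp & tc[, 2] %in% supp)) next
    v_split <- stats::setNames(numeric(P$n), P$rids)
    v_split[S] <- w
    v <- normalize_flux(unsplit_flux(v_split, net, P$split$pairs))
    mode <- flux_mode(v, net)
    sat <- satisfies(mode, cs, eps)
    if (!sat$ok) {
      nviol <- length(setdiff(sat$violations, "size"))
      if (nviol > 0L && nviol <= near_max_viol) {
        out$near[[length(out$near) + 1L]] <- supp
      }
      next
    }
    mode$verified_elementary <- is_elementary(mode, net)
    if (!mode$verified_elementary) next
    out$modes[[length(out$modes) + 1L]] <- mode
  }
  out
}

#' Serialize a constraint set to a JSON config
#' @export
write_constraint_set <- function(cs, path) {
  jsonlite::write_json(
    list(hard_active = cs$hard_active,
         forbidden_direction = cs$forbidden_direction,
         linear = cs$linear,
         max_support = if (is.finite(cs$max_support)) cs$max_support else NULL),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a constraint set from a JSON config
#' @export
read_constraint_set <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  constraint_set(
    hard_active = as.data.frame(x$hard_active),
    forbidden_direction = as.data.frame(x$forbidden_direction),
    linear = as.data.frame(x$linear),
    max_support = if (is.null(x$max_support)) Inf else x$max_support
  )
}
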