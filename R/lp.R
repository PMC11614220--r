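#' Solve a small dense linear program
#'
#' Minimizes (or maximizes) `obj %*% x` subject to `A_eq %*% x == b_eq`,
#' `A_ge %*% x >= b_ge` and box bounds `lb <= x <= ub`. Two independent
#' backends are provided: `"simplex"` (two-phase tableau simplex from
#' \pkg{boot}; returns a basic solution, i.e. a vertex of the feasible
#' polytope) and `"quadprog"` (strictly convex quadratic regularization
#' `min eps*||x||^2 + obj'x` solved with \pkg{quadprog}; returns the
#' minimum-norm point of the optimal face). Vertex solutions are what the
#' flux-mode machinery needs (minimal support); the quadratic backend serves
#' as an independent cross-check.
#'
#' All problems handled here are small and dense (at most a few hundred
#' variables); redundant equality rows are removed by QR factorization
#' before handing the system to the backend.
#'
#' @param obj numeric objective coefficients, length n.
#' @param A_eq,b_eq equality constraints (matrix m x n, vector m), or NULL.
#' @param A_ge,b_ge inequality constraints `A_ge x >= b_ge`, or NULL.
#' @param lb,ub box bounds, scalars or length-n vectors. `lb` must be finite;
#'   `ub` may be `Inf` only for the quadprog backend when the problem is
#'   otherwise bounded (the simplex backend requires finite `ub`).
#' @param maximize logical.
#' @param backend `"simplex"` or `"quadprog"`.
#' @return list with `status` ("optimal", "infeasible" or "unbounded"),
#'   `x` (solution, length n, NA if not optimal) and `objective`.
#' @keywords internal
solve_lp <- function(obj, A_eq = NULL, b_eq = NULL, A_ge = NULL, b_ge = NULL,
                     lb = 0, ub = 1000, maximize = FALSE,
                     backend = c("simplex", "quadprog")) {
  backend <- match.arg(backend)
  n <- length(obj)
  lb <- rep_len(lb, n)
  ub <- rep_len(ub, n)
  stopifnot(all(is.finite(lb)), all(ub >= lb))
  if (!is.null(A_eq)) {
    A_eq <- matrix(A_eq, ncol = n)
    red <- drop_dependent_rows(A_eq, b_eq)
    A_eq <- red$A
    b_eq <- red$b
    if (!red$consistent) {
      return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
    }
  }
  if (!is.null(A_ge)) A_ge <- matrix(A_ge, ncol = n)
  # variables pinned by their bounds are substituted out: degenerate
  # zero-width box rows destabilize the tableau solver
  fixed <- which(ub - lb < 1e-14)
  if (length(fixed)) {
    free <- setdiff(seq_len(n), fixed)
    xf <- lb[fixed]
    b_eq2 <- if (!is.null(A_eq)) b_eq - as.vector(A_eq[, fixed, drop = FALSE] %*% xf) else NULL
    b_ge2 <- if (!is.null(A_ge)) b_ge - as.vector(A_ge[, fixed, drop = FALSE] %*% xf) else NULL
    sub <- solve_lp(obj[free],
                    A_eq = if (is.null(A_eq)) NULL else A_eq[, free, drop = FALSE],
                    b_eq = b_eq2,
                    A_ge = if (is.null(A_ge)) NULL else A_ge[, free, drop = FALSE],
                    b_ge = b_ge2,
                    lb = lb[free], ub = ub[free], maximize = maximize,
                    backend = backend)
    x <- rep(NA_real_, n)
    if (sub$status == "optimal") {
      x[fixed] <- xf
      x[free] <- sub$x
      return(list(status = "optimal", x = x,
                  objective = sum(obj * x)))
    }
    return(list(status = sub$status, x = x, objective = NA_real_))
  }
  if (backend == "simplex") {
    out <- lp_simplex(obj, A_eq, b_eq, A_ge, b_ge, lb, ub, maximize)
    if (out$status != "optimal") {
      # the tableau solver is not reliable on every degenerate cone
      # problem; confirm any failure with the quadratic backend
      alt <- lp_quadprog(obj, A_eq, b_eq, A_ge, b_ge, lb, ub, maximize)
      if (alt$status == "optimal") out <- alt
    }
    out
  } else {
    lp_quadprog(obj, A_eq, b_eq, A_ge, b_ge, lb, ub, maximize)
  }
}

# Remove linearly dependent rows of an equality system; flags inconsistency
# (dependent row whose rhs does not follow from the kept rows).
drop_dependent_rows <- function(A, b, tol = 1e-9) {
  if (nrow(A) == 0L) return(list(A = A, b = b, consistent = TRUE))
  qrA <- qr(t(A))  # column pivoting on t(A) selects independent rows of A
  r <- qrA$rank
  keep <- qrA$pivot[seq_len(r)]
  A_red <- A[keep, , drop = FALSE]
  b_red <- b[keep]
  consistent <- TRUE
  if (r < nrow(A)) {
    # residual of dropped rows after projecting onto kept rows
    dropped <- setdiff(seq_len(nrow(A)), keep)
    coefs <- tryCatch(qr.solve(t(A_red), t(A[dropped, , drop = FALSE]), tol = 1e-12),
                      error = function(e) NULL)
    if (!is.null(coefs)) {
      b_pred <- as.vector(crossprod(coefs, b_red))
      scale <- max(1, abs(b))
      if (any(abs(b_pred - b[dropped]) > tol * scale)) consistent <- FALSE
    }
  }
  list(A = A_red, b = b_red, consistent = consistent)
}

lp_simplex <- function(obj, A_eq, b_eq, A_ge, b_ge, lb, ub, maximize) {
  n <- length(obj)
  if (any(!is.finite(ub))) {
    stop("simplex backend requires finite upper bounds")
  }
  # equilibrate: stoichiometric coefficients span several orders of
  # magnitude (protein coefficients ~1e-3, polymerization ~1e2), which
  # makes the dense tableau blow up numerically without scaling
  M <- rbind(A_eq, A_ge)
  col_scale <- rep(1, n)
  if (!is.null(M) && nrow(M)) {
    cmax <- apply(abs(M), 2, max)
    col_scale <- ifelse(cmax > 0, 1 / cmax, 1)
  }
  obj <- obj * col_scale
  lb <- lb / col_scale
  ub <- ub / col_scale
  scale_rows <- function(A, b) {
    if (is.null(A)) return(list(A = NULL, b = NULL))
    A <- sweep(A, 2, col_scale, `*`)
    rmax <- apply(abs(A), 1, max)
    rmax[rmax == 0] <- 1
    list(A = A / rmax, b = b / rmax)
  }
  eqs <- scale_rows(A_eq, b_eq)
  ges <- scale_rows(A_ge, b_ge)
  A_eq <- eqs$A; b_eq <- eqs$b
  A_ge <- ges$A; b_ge <- ges$b
  # shift x = y + lb so that y >= 0
  shift <- lb
  b_eq2 <- if (!is.null(A_eq)) b_eq - as.vector(A_eq %*% shift) else NULL
  b_ge2 <- if (!is.null(A_ge)) b_ge - as.vector(A_ge %*% shift) else NULL
  # upper bounds as y <= ub - lb, skipping redundant huge bounds is not safe
  # here (boundedness is required), so keep all.
  A1 <- diag(n)
  b1 <- ub - lb
  A2 <- NULL
  b2 <- NULL
  A3 <- NULL
  b3 <- NULL
  add_ge <- function(A, b) {
    # route rows with negative rhs to the <= block (negated) as boot::simplex
    # requires non-negative right-hand sides
    neg <- b < 0
    if (any(!neg)) {
      A2 <<- rbind(A2, A[!neg, , drop = FALSE])
      b2 <<- c(b2, b[!neg])
    }
    if (any(neg)) {
      A1 <<- rbind(A1, -A[neg, , drop = FALSE])
      b1 <<- c(b1, -b[neg])
    }
  }
  if (!is.null(A_ge)) add_ge(A_ge, b_ge2)
  if (!is.null(A_eq)) {
    sgn <- ifelse(b_eq2 < 0, -1, 1)
    A3 <- A_eq * sgn
    b3 <- b_eq2 * sgn
  }
  m_all <- nrow(A1) + NROW(A2) + NROW(A3)
  res <- tryCatch(
    boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                  A3 = A3, b3 = b3, maxi = maximize,
                  n.iter = 50L * (n + 2L * m_all), eps = 1e-10),
    error = function(e) NULL
  )
  if (is.null(res) || res$solved == -1) {
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  }
  if (res$solved != 1) {
    return(list(status = "unbounded", x = rep(NA_real_, n), objective = NA_real_))
  }
  x <- (as.vector(res$soln)[seq_len(n)] + shift) * col_scale
  list(status = "optimal", x = x, objective = sum((obj / col_scale) * x))
}

lp_quadprog <- function(obj, A_eq, b_eq, A_ge, b_ge, lb, ub, maximize,
                        reg = 1e-7) {
  n <- length(obj)
  # row-equilibrate the constraint blocks (see lp_simplex)
  scale_rows <- function(A, b) {
    if (is.null(A)) return(list(A = NULL, b = NULL))
    rmax <- apply(abs(A), 1, max)
    rmax[rmax == 0] <- 1
    list(A = A / rmax, b = b / rmax)
  }
  eqs <- scale_rows(A_eq, b_eq)
  ges <- scale_rows(A_ge, b_ge)
  A_eq <- eqs$A; b_eq <- eqs$b
  A_ge <- ges$A; b_ge <- ges$b
  cc <- if (maximize) obj else -obj
  scale <- max(1, abs(cc))
  solve_sub <- function(cols, reg_k) {
    nk <- length(cols)
    Ae <- if (!is.null(A_eq)) A_eq[, cols, drop = FALSE] else NULL
    if (!is.null(Ae)) {
      redk <- drop_dependent_rows(Ae, b_eq)
      if (!redk$consistent) return(NULL)
      Ae <- redk$A
      be <- redk$b
    } else be <- NULL
    Ag <- if (!is.null(A_ge)) A_ge[, cols, drop = FALSE] else NULL
    ubk <- ub[cols]
    Amat <- t(rbind(Ae, Ag, diag(nk),
                    if (any(is.finite(ubk)))
                      -diag(nk)[is.finite(ubk), , drop = FALSE] else NULL))
    bvec <- c(be, b_ge, lb[cols],
              if (any(is.finite(ubk))) -ubk[is.finite(ubk)])
    meq <- if (is.null(Ae)) 0L else nrow(Ae)
    tryCatch(
      quadprog::solve.QP(diag(reg_k * scale, nk), cc[cols], Amat, bvec,
                         meq = meq),
      error = function(e) e
    )
  }
  # adaptive regularization: the Goldfarb-Idnani solver needs a
  # sufficiently large quadratic term on ill-conditioned systems; a
  # support-restricted polish then removes the regularization bias
  cols <- seq_len(n)
  sol <- NULL
  reg_used <- reg
  for (reg_k in c(reg, 1e-5, 1e-3, 1e-1)) {
    s <- solve_sub(cols, reg_k)
    if (!inherits(s, "error") && !is.null(s)) { sol <- s; reg_used <- reg_k; break }
  }
  if (is.null(sol)) {
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  }
  x <- numeric(n)
  x[cols] <- sol$solution
  # polish: restrict to the active support and re-solve with a weaker
  # quadratic term; repeat while the support shrinks
  for (pass in 1:4) {
    sup <- which(x > 1e-9 * max(abs(x), 1) | lb > 0)
    if (length(sup) == length(cols) && pass > 1) break
    cols2 <- sup
    done <- FALSE
    for (reg_k in c(reg, 1e-5, 1e-3)) {
      s <- solve_sub(cols2, reg_k)
      if (!inherits(s, "error") && !is.null(s)) {
        x2 <- numeric(n)
        x2[cols2] <- s$solution
        if (sum(cc * x2) >= sum(cc * x) - 1e-9 * scale) x <- x2
        done <- TRUE
        break
      }
    }
    if (!done) break
    cols <- cols2
  }
  x <- pmin(pmax(x, lb), ifelse(is.finite(ub), ub, x))
  list(status = "optimal", x = x, objective = sum(obj * x))
}

#' Null space of a matrix
#'
#' Orthonormal basis of `{x : A x = 0}` computed from the SVD, with singular
#' values below `tol * max(singular value)` treated as zero.
#'
#' @keywords internal
null_space <- function(A, tol = 1e-9) {
  if (nrow(A) == 0L) return(diag(ncol(A)))
  sv <- svd(A, nu = 0, nv = ncol(A))
  positive <- sv$d > tol * max(sv$d, .Machine$double.eps)
  r <- sum(positive)
  if (r == ncol(A)) {
    matrix(0, ncol(A), 0)
  } else {
    sv$v[, (r + 1L):ncol(A), drop = FALSE]
  }
}

#' Numerical rank via singular values
#' @keywords internal
mat_rank <- function(A, tol = 1e-9) {
  if (length(A) == 0L || nrow(A) == 0L || ncol(A) == 0L) return(0L)
  d <- svd(A, nu = 0, nv = 0)$d
  sum(d > tol * max(d, .Machine$double.eps))
}

# Seeded RNG evaluation that restores the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
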