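#' Mean exometabolomic exchange fluxes of the NCI-60 cancer cell lines
#'
#' Packaged constants: mean and standard deviation of exchange fluxes in
#' fmol/cell/h (negative = uptake, positive = secretion) across the sixty
#' cell lines, together with the directional category each metabolite
#' contributes to the constraint set. `sign` is the observed direction
#' (`"-"` uptake, `"+"` secretion, `"+/-"` both occur); `constraint_type`
#' separates the hard constraints (glucose, lactate, glutamine) from
#' desired observations and unconstrained metabolites; `status` records
#' metabolites without usable numbers (pyruvate uncalibrated; formate and
#' histidine missing), which are excluded from regressions.
#'
#' @return data frame of class `exometab_table` with columns `metabolite`,
#'   `mean`, `sd`, `sign`, `constraint_type`, `status`, `category`.
#' @export
table1_constants <- function() {
  t1 <- read.table(header = TRUE, stringsAsFactors = FALSE, text = '
metabolite    mean     sd     sign  constraint_type status
glucose      -326.87 196.12   -     hard            ok
lactate       442.20 289.40   +     hard            ok
glutamine     -82.48  56.20   -     hard            ok
glutamate      13.54  16.99   +     desired         ok
serine        -11.57   7.05   -     desired         ok
glycine         0.96   2.97   +/-   unconstrained   ok
alanine        15.89  13.34   +     desired         ok
proline         1.21   1.49   +/-   unconstrained   ok
asp_asn        -3.33   3.39   -     desired         ok
arginine       -4.90   4.44   -     desired         ok
tiv           -14.90   7.99   -     desired         ok
yflkw         -19.80  10.57   -     desired         ok
xtp             0.10   0.22   +/-   unconstrained   ok
pyruvate          NA     NA   +     desired         uncalibrated
formate           NA     NA   +/-   unconstrained   missing
histidine         NA     NA   -     desired         missing
cysteine        0.05   0.08   +/-   unconstrained   ok
methionine     -2.11   1.23   +/-   unconstrained   ok')
  t1$category <- ifelse(t1$status == "ok", t1$constraint_type, "missing")
  class(t1) <- c("exometab_table", "data.frame")
  t1
}

#' Exchange fluxes of a mode for the measured metabolites
#'
#' @param mode [flux_mode()] or named flux vector.
#' @param table an `exometab_table`, see [table1_constants()].
#' @param net a [metabolic_network()].
#' @param aliases metabolite-key to model-id mapping.
#' @return named numeric vector over the table's metabolite keys (uptake
#'   negative), `NA` where the network has no exchange for a metabolite.
#' @export
mode_exchange_vector <- function(mode, table, net,
                                 aliases = default_exchange_aliases()) {
  vapply(table$metabolite, function(m) {
    if (!m %in% names(aliases)) return(NA_real_)
    tryCatch(exchange_flux(mode, m, net, aliases), error = function(e) NA_real_)
  }, 0)
}

#' Linear-regression score of a flux mode against exchange-flux data
#'
#' Ordinary least squares (with intercept) of the measured mean fluxes on
#' the mode's exchange values, restricted to metabolites with usable data
#' and nonzero mode flux. Regressing the data (fmol/cell/h) on the
#' dimensionless mode values makes the RMSE carry data units and the score
#' invariant under positive rescaling of the mode; `direction =
#' "mode_on_data"` swaps the roles for sensitivity checks.
#'
#' @param mode [flux_mode()] or named flux vector on `net`.
#' @param table an `exometab_table` (see [table1_constants()]).
#' @param net the network the mode lives on.
#' @param aliases metabolite-key to model-id mapping.
#' @param direction which variable is regressed on which.
#' @return object of class `regression_score`: `r2`, `rmse`, `slope`,
#'   `intercept`, `n_points`.
#' @export
regress_mode <- function(mode, table, net,
                         aliases = default_exchange_aliases(),
                         direction = c("data_on_mode", "mode_on_data")) {
  direction <- match.arg(direction)
  x <- mode_exchange_vector(mode, table, net, aliases)
  y <- table$mean
  usable <- table$status == "ok" & !is.na(x) & abs(x) > 0
  x <- x[usable]
  y <- y[usable]
  if (direction == "mode_on_data") { tmp <- x; x <- y; y <- tmp }
  if (length(x) < 2L) {
    stop("undefined regression score: fewer than 2 usable exchange fluxes")
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  res <- fit$residuals
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else as.numeric(ss_res < 1e-12)
  structure(list(r2 = r2, rmse = sqrt(mean(res^2)),
                 slope = unname(fit$coefficients[2L]),
                 intercept = unname(fit$coefficients[1L]),
                 n_points = length(x)),
            class = "regression_score")
}

#' @export
print.regression_score <- function(x, ...) {
  cat(sprintf("regression_score: R2 = %.4f, RMSE = %.2f (n = %d, slope = %.3g)\n",
              x$r2, x$rmse, x$n_points, x$slope))
  invisible(x)
}

#' Rank flux modes by regression fit
#'
#' Scores every mode with [regress_mode()] and orders them by descending
#' R-squared, ties broken by ascending RMSE then by index.
#'
#' @param modes list of [flux_mode()].
#' @inheritParams regress_mode
#' @return data frame with columns `index`, `r2`, `rmse`, `slope`,
#'   `intercept`, `n_points`, one row per mode, best first.
#' @export
rank_modes <- function(modes, table, net,
                       aliases = default_exchange_aliases(),
                       direction = "data_on_mode") {
  scores <- lapply(modes, regress_mode, table = table, net = net,
                   aliases = aliases, direction = direction)
  df <- data.frame(
    index = seq_along(modes),
    r2 = vapply(scores, `[[`, 0, "r2"),
    rmse = vapply(scores, `[[`, 0, "rmse"),
    slope = vapply(scores, `[[`, 0, "slope"),
    intercept = vapply(scores, `[[`, 0, "intercept"),
    n_points = vapply(scores, `[[`, 0L, "n_points")
  )
  df[order(-df$r2, df$rmse, df$index), , drop = FALSE]
}

#' Per-cell-line first places of a set of modes
#'
#' Scores each mode against each cell line's individual exchange fluxes and
#' counts, for every mode, the number of lines on which it ranks first
#' (descending R-squared, RMSE/index tie-break). Lines with fewer than two
#' usable metabolites are skipped with a warning.
#'
#' @param modes list of [flux_mode()].
#' @param per_line numeric matrix, rows = cell lines, columns named by the
#'   table's metabolite keys (fmol/cell/h, uptake negative).
#' @inheritParams regress_mode
#' @return list with `first_places` (named integer vector per mode index),
#'   `mean_r2` (average R-squared per mode across used lines), `best_mode`
#'   (index with most firsts) and `n_lines_used`.
#' @export
per_line_first_places <- function(modes, per_line, table, net,
                                  aliases = default_exchange_aliases()) {
  stopifnot(is.matrix(per_line), !is.null(colnames(per_line)))
  firsts <- stats::setNames(integer(length(modes)), seq_along(modes))
  r2sum <- numeric(length(modes))
  used <- 0L
  for (li in seq_len(nrow(per_line))) {
    tab <- table
    hit <- match(tab$metabolite, colnames(per_line))
    tab$mean <- ifelse(is.na(hit), NA, per_line[li, hit])
    tab$status <- ifelse(is.na(tab$mean), "missing", "ok")
    if (sum(tab$status == "ok") < 2L) {
      warning("cell line ", rownames(per_line)[li] %||% li,
              " skipped: fewer than 2 usable metabolites")
      next
    }
    rk <- rank_modes(modes, tab, net, aliases)
    firsts[rk$index[1L]] <- firsts[rk$index[1L]] + 1L
    r2sum[rk$index] <- r2sum[rk$index] + rk$r2
    used <- used + 1L
  }
  list(first_places = firsts, mean_r2 = r2sum / max(used, 1L),
       best_mode = as.integer(names(which.max(firsts))), n_lines_used = used)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summary statistics of exchange fluxes across a set of modes
#'
#' Per measured metabolite: minimum, maximum, mean, median and standard
#' deviation of the modes' exchange fluxes (uptake negative). Modes are
#' used at their stored normalization.
#'
#' @inheritParams rank_modes
#' @return data frame, one row per metabolite key.
#' @export
summarize_exchanges <- function(modes, net, table = table1_constants(),
                                aliases = default_exchange_aliases()) {
  stopifnot(length(modes) > 0)
  E <- t(vapply(modes, mode_exchange_vector, numeric(nrow(table)),
                table = table, net = net, aliases = aliases))
  colnames(E) <- table$metabolite
  data.frame(
    metabolite = table$metabolite,
    min = apply(E, 2, min), max = apply(E, 2, max),
    mean = colMeans(E), median = apply(E, 2, stats::median),
    sd = apply(E, 2, stats::sd),
    row.names = NULL
  )
}

#' Score a matrix of flux vectors against an exchange-flux table
#'
#' Vectorized regression scoring for large flux samples: each row of `X` is
#' a flux vector over `net`'s reactions; returns R-squared and RMSE per row
#' under the same conventions as [regress_mode()]. Rows with fewer than two
#' usable points get `NA`.
#'
#' @param X numeric matrix, columns named by reaction ids.
#' @inheritParams regress_mode
#' @export
score_flux_matrix <- function(X, table, net,
                              aliases = default_exchange_aliases()) {
  ok <- which(table$status == "ok")
  # linear map from reaction fluxes to boundary-species production rates
  W <- NULL
  keys <- character(0)
  for (i in ok) {
    m <- aliases[[table$metabolite[i]]]
    d <- tryCatch(uptake_direction(net, m), error = function(e) NULL)
    if (is.null(d)) next
    w <- numeric(ncol(X))
    w[match(d$rxn, colnames(X))] <- d$coef
    W <- cbind(W, w)
    keys <- c(keys, table$metabolite[i])
  }
  E <- X %*% W
  y_all <- table$mean[match(keys, table$metabolite)]
  out <- matrix(NA_real_, nrow(X), 2, dimnames = list(NULL, c("r2", "rmse")))
  for (i in seq_len(nrow(E))) {
    x <- E[i, ]
    use <- abs(x) > 1e-9 * max(abs(x), 1e-300)
    if (sum(use) < 2L) next
    xs <- x[use]
    ys <- y_all[use]
    fit <- stats::lm.fit(cbind(1, xs), ys)
    ss_tot <- sum((ys - mean(ys))^2)
    ss_res <- sum(fit$residuals^2)
    out[i, 1] <- if (ss_tot > 0) 1 - ss_res / ss_tot else as.numeric(ss_res < 1e-12)
    out[i, 2] <- sqrt(mean(fit$residuals^2))
  }
  out
}

#' Export mode scores as CSV
#' @export
write_scores_csv <- function(ranking, path) {
  utils::write.csv(ranking, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-cell-line exchange-flux matrix from CSV
#'
#' Rows = cell lines (first column taken as line names), columns =
#' metabolite keys, fluxes in fmol/cell/h with uptake negative.
#' @export
read_per_line_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
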