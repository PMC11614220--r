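#' Generate synthetic per-cell-line exchange-flux tables
#'
#' Draws `n_lines` cell lines with exchange fluxes Normal(mean, sd) per
#' metabolite from the table's statistics (fmol/cell/h). With
#' `enforce_signs`, draws violating a metabolite's directional category
#' ("-" uptake-only, "+" secretion-only) are redrawn from the same
#' distribution (up to 100 attempts, then clipped to zero), i.e. a
#' truncated-normal emulation that keeps the distribution shape. Each line
#' gets a synthetic cancer-type label (round-robin over nine types) to
#' exercise per-type aggregation.
#'
#' @param table an `exometab_table`; rows without numeric means are skipped.
#' @param n_lines number of cell lines (default 60).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @param enforce_signs clip draws to the metabolite's category.
#' @return numeric matrix `n_lines x metabolites` with metabolite-key
#'   columns, line names `line_01...`, and attribute `cancer_type`.
#' @export
generate_cell_lines <- function(table, n_lines = 60L, seed = 1L,
                                enforce_signs = TRUE) {
  stopifnot(n_lines >= 1L)
  ok <- table[table$status == "ok", ]
  with_seed(seed, {
    M <- matrix(NA_real_, n_lines, nrow(ok),
                dimnames = list(sprintf("line_%02d", seq_len(n_lines)),
                                ok$metabolite))
    for (j in seq_len(nrow(ok))) {
      x <- stats::rnorm(n_lines, ok$mean[j], ok$sd[j])
      if (enforce_signs && ok$sign[j] %in% c("-", "+")) {
        bad_dir <- if (ok$sign[j] == "-") function(z) z > 0 else function(z) z < 0
        for (attempt in seq_len(100L)) {
          bad <- bad_dir(x)
          if (!any(bad)) break
          x[bad] <- stats::rnorm(sum(bad), ok$mean[j], ok$sd[j])
        }
        x[bad_dir(x)] <- 0
      }
      M[, j] <- x
    }
    attr(M, "cancer_type") <-
      rep(c("Breast", "CNS", "Colon", "Leukemia", "Melanoma", "NSCLC",
            "Ovarian", "Prostate", "Renal"), length.out = n_lines)
    M
  })
}

#' Generate planted-mode exchange data
#'
#' Parameter-recovery harness: each synthetic line is a positive scaling of
#' one flux mode's exchange vector plus Gaussian noise, so the planted mode
#' should win the per-line regression ranking when the noise is small.
#'
#' @param mode the planted [flux_mode()].
#' @param net network the mode lives on.
#' @param table exometabolomics table defining the measured metabolites.
#' @param scale_range interval for the uniform per-line scaling factor.
#' @param noise_sd Gaussian noise standard deviation (same units as the
#'   scaled exchange values).
#' @param n_lines number of lines.
#' @param seed integer seed.
#' @param aliases metabolite-key to model-id mapping.
#' @return numeric matrix `n_lines x metabolites` (metabolite-key columns).
#' @export
generate_planted_efm_data <- function(mode, net, table = table1_constants(),
                                      scale_range = c(50, 200),
                                      noise_sd = 1, n_lines = 60L, seed = 1L,
                                      aliases = default_exchange_aliases()) {
  ex <- mode_exchange_vector(mode, table, net, aliases)
  ex <- ex[table$status == "ok"]
  if (sum(ex != 0, na.rm = TRUE) < 3L) {
    stop("planted mode has fewer than 3 nonzero measured exchange fluxes")
  }
  with_seed(seed, {
    ci <- stats::runif(n_lines, scale_range[1], scale_range[2])
    M <- outer(ci, ex) +
      matrix(stats::rnorm(n_lines * length(ex), 0, noise_sd), n_lines)
    dimnames(M) <- list(sprintf("line_%02d", seq_len(n_lines)), names(ex))
    M
  })
}

#' Generate toy stoichiometric networks with known EFM sets
#'
#' Fixtures for the enumeration oracles:
#' \itemize{
#' \item `chain`: a linear pathway in -> M1 -> ... -> out with `size`
#'   reactions total and exactly one EFM;
#' \item `diamond`: one input, two parallel internal routes, one output
#'   (two EFMs);
#' \item `cycle`: an internal cycle of length `size` plus an entry and an
#'   exit exchange;
#' \item `random`: a connected random network built around a guaranteed
#'   substrate-to-product path (hence at least one EFM) with extra random
#'   reactions, some reversible.
#' }
#'
#' @param kind network family.
#' @param size number of reactions (chain/random) or cycle length (cycle).
#' @param seed integer seed (random kind).
#' @return a [metabolic_network()].
#' @export
generate_toy_network <- function(kind = c("chain", "diamond", "cycle", "random"),
                                 size = 6L, seed = 1L) {
  kind <- match.arg(kind)
  switch(kind,
    chain = {
      stopifnot(size >= 2L)
      k <- size - 2L  # internal conversions
      ids <- paste0("M", seq_len(k + 1L))
      mets <- rbind(metabolite(c("Sx", "Px"), compartment = "external",
                               boundary = TRUE),
                    metabolite(ids))
      rxns <- c(list(reaction("EX_in", c(Sx = -1, M1 = 1))),
                lapply(seq_len(k), function(i)
                  reaction(paste0("R", i),
                           stats::setNames(c(-1, 1), ids[c(i, i + 1L)]))),
                list(reaction("EX_out",
                              stats::setNames(c(-1, 1), c(ids[k + 1L], "Px")))))
      metabolic_network(mets, rxns)
    },
    diamond = {
      mets <- rbind(metabolite(c("Sx", "Px"), compartment = "external",
                               boundary = TRUE),
                    metabolite(c("A", "B1", "B2", "C")))
      metabolic_network(mets, list(
        reaction("EX_in", c(Sx = -1, A = 1)),
        reaction("UP", c(A = -1, B1 = 1)),
        reaction("DOWN", c(A = -1, B2 = 1)),
        reaction("UPJOIN", c(B1 = -1, C = 1)),
        reaction("DOWNJOIN", c(B2 = -1, C = 1)),
        reaction("EX_out", c(C = -1, Px = 1))
      ))
    },
    cycle = {
      stopifnot(size >= 2L)
      ids <- paste0("C", seq_len(size))
      mets <- rbind(metabolite(c("Sx", "Px"), compartment = "external",
                               boundary = TRUE),
                    metabolite(ids))
      rxns <- c(
        list(reaction("EX_in", c(Sx = -1, C1 = 1))),
        lapply(seq_len(size), function(i) {
          to <- if (i == size) 1L else i + 1L
          reaction(paste0("R", i),
                   stats::setNames(c(-1, 1), ids[c(i, to)]))
        }),
        list(reaction("EX_out", c(C1 = -1, Px = 1)))
      )
      metabolic_network(mets, rxns)
    },
    random = {
      stopifnot(size >= 4L)
      n_int <- max(2L, floor(size / 2L))
      ids <- paste0("M", seq_len(n_int))
      mets <- rbind(metabolite(c("Sx", "Px"), compartment = "external",
                               boundary = TRUE),
                    metabolite(ids))
      with_seed(seed, {
        # guaranteed path through all internal metabolites
        rxns <- c(
          list(reaction("EX_in", c(Sx = -1, M1 = 1))),
          lapply(seq_len(n_int - 1L), function(i)
            reaction(paste0("P", i),
                     stats::setNames(c(-1, 1), ids[c(i, i + 1L)]))),
          list(reaction("EX_out",
                        stats::setNames(c(-1, 1), c(ids[n_int], "Px"))))
        )
        extra <- size - length(rxns)
        k <- 0L
        while (k < extra) {
          k <- k + 1L
          from_to <- sample(n_int, 2L)
          rxns[[length(rxns) + 1L]] <- reaction(
            paste0("X", k),
            stats::setNames(c(-1, 1), ids[from_to]),
            reversible = stats::runif(1) < 0.3)
        }
        metabolic_network(mets, rxns)
      })
    })
}
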