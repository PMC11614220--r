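#' Run the full constrained-EFM analysis pipeline
#'
#' Orchestrates: model construction (or SBML load) -> compression ->
#' constrained EFM sampling -> regression ranking against exchange-flux
#' data -> optional parsimonious FBA and hit-and-run flux-sampling
#' comparison -> optional per-line analysis on synthetic cell lines.
#' Artifacts (CSV matrices, a JSON summary, a provenance record and a stage
#' log) are written to `config$out_dir` when given; the summary list is
#' returned invisibly either way.
#'
#' @param config list with (all optional) entries: `model` ("synthetic" or a
#'   path to an SBML file), `n_efms`, `seed`, `time_limit`, `max_support`,
#'   `pfba` (flag), `flux_bound`, `sampling_n` (vector of sample sizes, or
#'   NULL to skip), `per_line_n` (number of synthetic cell lines, or NULL to
#'   skip), `out_dir`, `dry_run`.
#' @return summary list with model/compression counts, score ranges, the
#'   best mode, and baseline comparisons.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(list(
    model = "synthetic", n_efms = 100L, seed = 1L, time_limit = Inf,
    max_support = 60L, pfba = TRUE, flux_bound = 15,
    sampling_n = NULL, per_line_n = NULL, out_dir = NULL, dry_run = FALSE
  ), config)
  if (isTRUE(cfg$dry_run)) {
    message("dry run: configuration echo only")
    return(invisible(cfg))
  }
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  log <- character()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    dt <- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    log <<- c(log, sprintf("%s: %.2fs", name, dt))
    res
  }

  net <- stage("model", {
    if (identical(cfg$model, "synthetic")) synthetic_stroma_model()
    else read_sbml(cfg$model)
  })
  table <- table1_constants()
  comp <- stage("compression", compress(net))
  cnet <- comp$network
  cs <- stage("constraints",
              default_constraint_set(cnet, table,
                                     max_support = cfg$max_support))
  modes_c <- stage("efm_sampling",
                   sample_constrained_efms(cnet, cs, n = cfg$n_efms,
                                           seed = cfg$seed,
                                           time_limit = cfg$time_limit))
  modes <- stage("decompression",
                 lapply(modes_c, function(m) {
                   fm <- flux_mode(decompress(m$v, comp$map, net), net)
                   fm$verified_elementary <- m$verified_elementary
                   fm
                 }))
  ranking <- stage("scoring", rank_modes(modes_c, table, cnet))
  best <- modes_c[[ranking$index[1L]]]

  summary <- list(
    model = list(reactions = length(net$reactions),
                 metabolites = nrow(net$metabolites),
                 internal_metabolites = sum(!net$metabolites$boundary),
                 exchange_reactions = length(exchange_reactions(net))),
    compressed = list(reactions = length(cnet$reactions),
                      internal_metabolites = sum(!cnet$metabolites$boundary),
                      external_metabolites = sum(cnet$metabolites$boundary),
                      blocked = length(comp$map$blocked)),
    efms = list(n = length(modes_c),
                r2_max = max(ranking$r2), r2_min = min(ranking$r2),
                rmse_min = min(ranking$rmse), rmse_max = max(ranking$rmse),
                best_index = ranking$index[1L],
                best_support = length(best$support)),
    seeds = list(efm = cfg$seed)
  )

  # pFBA and flux sampling run on the uncompressed network (plain LPs do
  # not need compression, and the printed objective reactions live there)
  cs_full <- NULL
  if (isTRUE(cfg$pfba) || !is.null(cfg$sampling_n)) {
    cs_full <- stage("constraints_full",
                     default_constraint_set(net, table,
                                            max_support = cfg$max_support))
  }
  if (isTRUE(cfg$pfba)) {
    sol <- stage("pfba", pfba(net, cs_full, flux_bound = cfg$flux_bound))
    pr2 <- tryCatch(
      regress_mode(sol$fluxes, table, net)$r2, error = function(e) NA_real_)
    summary$pfba <- list(status = sol$status,
                         objective = sol$objective_value,
                         total_flux = sol$total_flux, r2 = pr2)
  }
  if (!is.null(cfg$sampling_n)) {
    summary$flux_sampling <- lapply(cfg$sampling_n, function(ns) {
      X <- stage(paste0("flux_sampling_", ns),
                 flux_sample(net, cs_full, n = ns, seed = cfg$seed + 1L,
                             flux_bound = cfg$flux_bound))
      sc <- score_flux_matrix(X, table, net)
      list(n = ns, r2_max = max(sc[, "r2"], na.rm = TRUE),
           r2_median = stats::median(sc[, "r2"], na.rm = TRUE))
    })
  }
  if (!is.null(cfg$per_line_n)) {
    lines <- stage("per_line_data",
                   generate_cell_lines(table, n_lines = cfg$per_line_n,
                                       seed = cfg$seed + 2L))
    pl <- stage("per_line_scoring",
                per_line_first_places(modes_c, lines, table, cnet))
    summary$per_line <- list(best_mode = pl$best_mode,
                             firsts = max(pl$first_places),
                             n_lines = pl$n_lines_used)
  }

  if (!is.null(out_dir)) {
    write_efm_csv(modes, file.path(out_dir, "efms.csv"))
    write_scores_csv(ranking, file.path(out_dir, "scores.csv"))
    write_compression_map(comp$map, file.path(out_dir, "compression_map.json"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cfg_path <- file.path(out_dir, "config.json")
    jsonlite::write_json(cfg[order(names(cfg))], cfg_path, auto_unbox = TRUE,
                         null = "null", digits = NA)
    prov <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                 seeds = summary$seeds,
                 package_version = as.character(utils::packageVersion("stromaefm")))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE)
    writeLines(log, file.path(out_dir, "stages.log"))
  }
  invisible(summary)
}
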