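test_that("the packaged exchange-flux table matches the published statistics", {
  t1 <- table1_constants()
  expect_equal(t1$mean[t1$metabolite == "glucose"], -326.87)
  expect_equal(t1$sd[t1$metabolite == "glucose"], 196.12)
  expect_equal(t1$mean[t1$metabolite == "lactate"], 442.20)
  expect_equal(t1$mean[t1$metabolite == "glutamine"], -82.48)
  expect_equal(t1$mean[t1$metabolite == "methionine"], -2.11)
  # missing / uncalibrated entries carry no numbers but keep their signs
  expect_true(is.na(t1$mean[t1$metabolite == "histidine"]))
  expect_equal(t1$category[t1$metabolite == "histidine"], "missing")
  expect_equal(t1$sign[t1$metabolite == "histidine"], "-")
  expect_equal(t1$status[t1$metabolite == "pyruvate"], "uncalibrated")
  # 15 metabolites carry numeric means
  expect_equal(sum(!is.na(t1$mean)), 15L)
  expect_equal(t1$constraint_type[t1$metabolite %in%
                                    c("glucose", "lactate", "glutamine")],
               rep("hard", 3))
})

test_that("regression scores are exact on synthetic proportional data", {
  net <- stroma_net()
  tab <- table1_constants()
  al <- default_exchange_aliases()
  # craft a flux vector whose exchange values are exactly mean/2
  v <- stats::setNames(numeric(length(net$reactions)),
                       vapply(net$reactions, `[[`, "", "id"))
  for (i in which(tab$status == "ok")) {
    d <- uptake_direction(net, al[[tab$metabolite[i]]])
    v[d$rxn] <- tab$mean[i] / 2
  }
  # orient each exchange so its uptake-negative value equals mean/2
  for (i in which(tab$status == "ok")) {
    d <- uptake_direction(net, al[[tab$metabolite[i]]])
    got <- exchange_flux(v, tab$metabolite[i], net, al)
    if (abs(got - tab$mean[i] / 2) > 1e-9) v[d$rxn] <- -v[d$rxn]
  }
  sc <- regress_mode(v, tab, net)
  expect_equal(sc$r2, 1, tolerance = 1e-12)
  expect_equal(sc$rmse, 0, tolerance = 1e-9)
  expect_equal(sc$slope, 2, tolerance = 1e-9)
  expect_equal(sc$n_points, 15L)
  # positive rescaling leaves the score unchanged (slope absorbs scale)
  sc2 <- regress_mode(17.3 * v, tab, net)
  expect_equal(sc2$r2, sc$r2)
  expect_equal(sc2$rmse, sc$rmse)
  expect_equal(sc2$slope, sc$slope / 17.3, tolerance = 1e-9)
  # too few usable points is an error
  v2 <- v * 0
  v2["EX_GLUC"] <- 1
  expect_error(regress_mode(v2, tab, net), "fewer than 2")
})

test_that("scale invariance holds for sampled modes", {
  cnet <- stroma_compressed()$network
  tab <- table1_constants()
  m <- stroma_modes()[[1]]
  a <- regress_mode(m, tab, cnet)
  b <- regress_mode(flux_mode(0.01 * m$v, cnet), tab, cnet)
  expect_equal(a$r2, b$r2, tolerance = 1e-9)
  expect_equal(a$rmse, b$rmse, tolerance = 1e-6)
})

test_that("rank_modes orders by fit and is a permutation", {
  cnet <- stroma_compressed()$network
  modes <- stroma_modes()
  rk <- rank_modes(modes, table1_constants(), cnet)
  expect_setequal(rk$index, seq_along(modes))
  expect_true(all(diff(rk$r2) <= 1e-12))
  single <- rank_modes(modes[2], table1_constants(), cnet)
  expect_equal(single$index, 1L)
})

test_that("per-line first places recover a planted mode", {
  cnet <- stroma_compressed()$network
  modes <- stroma_modes()[seq_len(min(8, length(stroma_modes())))]
  planted_idx <- 2L
  per_line <- generate_planted_efm_data(modes[[planted_idx]], cnet,
                                        noise_sd = 0.1, n_lines = 15,
                                        seed = 5)
  res <- per_line_first_places(modes, per_line, table1_constants(), cnet)
  expect_equal(res$best_mode, planted_idx)
  expect_equal(unname(res$first_places[planted_idx]), 15L)
  expect_equal(res$n_lines_used, 15L)
  expect_equal(which.max(res$mean_r2), planted_idx)
  # single-mode input trivially takes every line
  solo <- per_line_first_places(modes[1], per_line, table1_constants(), cnet)
  expect_equal(unname(solo$first_places), 15L)
  # a line with too few usable values is skipped with a warning
  broken <- per_line
  broken[3, ] <- NA
  broken[3, "glucose"] <- -100
  expect_warning(per_line_first_places(modes[1], broken, table1_constants(),
                                       cnet), "skipped")
})

test_that("exchange summaries degenerate correctly for a single mode", {
  cnet <- stroma_compressed()$network
  one <- stroma_modes()[1]
  s <- summarize_exchanges(one, cnet)
  expect_true(all(is.na(s$sd) | s$sd == 0))
  expect_equal(s$min, s$max)
  many <- summarize_exchanges(stroma_modes(), cnet)
  expect_true(all(many$min <= many$median & many$median <= many$max,
                  na.rm = TRUE))
})

test_that("score_flux_matrix agrees with regress_mode row by row", {
  cnet <- stroma_compressed()$network
  modes <- stroma_modes()[seq_len(min(6, length(stroma_modes())))]
  X <- do.call(rbind, lapply(modes, function(m) m$v))
  sc <- score_flux_matrix(X, table1_constants(), cnet)
  for (i in seq_along(modes)) {
    ref <- regress_mode(modes[[i]], table1_constants(), cnet)
    expect_equal(unname(sc[i, "r2"]), ref$r2, tolerance = 1e-8)
    expect_equal(unname(sc[i, "rmse"]), ref$rmse, tolerance = 1e-6)
  }
})
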