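test_that("blocked reactions are exactly the ones no steady flux can carry", {
  # dead-end production: nothing consumes D
  mets <- rbind(metabolite(c("Sx", "Px"), compartment = "external",
                           boundary = TRUE),
                metabolite(c("A", "D")))
  net <- metabolic_network(mets, list(
    reaction("EX_in", c(Sx = -1, A = 1)),
    reaction("EX_out", c(A = -1, Px = 1)),
    reaction("DEAD", c(A = -1, D = 1))
  ))
  expect_equal(find_blocked_reactions(net), "DEAD")

  # five-reaction chain with one disconnected conversion
  mets2 <- rbind(metabolite(c("Sx", "Px"), compartment = "external",
                            boundary = TRUE),
                 metabolite(c("A", "B", "U", "V")))
  net2 <- metabolic_network(mets2, list(
    reaction("EX_in", c(Sx = -1, A = 1)),
    reaction("R1", c(A = -1, B = 1)),
    reaction("EX_out", c(B = -1, Px = 1)),
    reaction("ISOLATED", c(U = -1, V = 1)),
    reaction("ISOLATED2", c(V = -1, U = 1))
  ))
  # the isolated two-cycle can carry flux (it is internally balanced);
  # making one direction irreversible-only blocks nothing, but removing
  # the return reaction strands both
  net3 <- metabolic_network(mets2, net2$reactions[1:4])
  expect_equal(find_blocked_reactions(net3), "ISOLATED")
  expect_equal(find_blocked_reactions(generate_toy_network("cycle", 3)),
               character(0))
})

test_that("a linear chain compresses to a single reaction", {
  chain <- generate_toy_network("chain", 5)
  out <- compress(chain)
  expect_length(out$network$reactions, 1L)
  expect_length(out$map$subsets, 1L)
  expect_equal(sort(out$map$subsets[[1]]$members),
               sort(vapply(chain$reactions, `[[`, "", "id")))
  expect_equal(unname(out$map$subsets[[1]]$ratios),
               rep(1, 5))
})

test_that("every original reaction lands in exactly one subset or blocked", {
  for (net in list(stroma_net(), generate_toy_network("diamond"),
                   generate_toy_network("random", 12, seed = 4))) {
    out <- compress(net)
    placed <- c(unlist(lapply(out$map$subsets, `[[`, "members")),
                out$map$blocked)
    expect_setequal(placed, vapply(net$reactions, `[[`, "", "id"))
    expect_equal(anyDuplicated(placed), 0L)
  }
})

test_that("compression is idempotent", {
  out <- compress(stroma_net())
  again <- compress(out$network)
  expect_length(again$network$reactions, length(out$network$reactions))
  expect_equal(length(again$map$blocked), 0L)
  expect_true(all(vapply(again$map$subsets,
                         function(s) length(s$members) == 1L, NA)))
})

test_that("decompression inverts compression and preserves steady state", {
  net <- stroma_net()
  out <- compress(net)
  modes <- stroma_modes()
  for (m in modes[seq_len(min(5, length(modes)))]) {
    v <- decompress(m$v, out$map, net)
    expect_true(is_steady_state(v, net, tol = 1e-8))
  }
  # zero maps to zero; unknown ids error
  z <- decompress(stats::setNames(numeric(0), character(0)), out$map, net)
  expect_true(all(z == 0))
  expect_error(decompress(c(NOT_A_SUBSET = 1), out$map), "unknown compressed")
})

test_that("EFMs of the compressed network decompress to the original EFM set", {
  for (seed in c(2, 5)) {
    toy <- generate_toy_network("random", 11, seed = seed)
    out <- compress(toy)
    direct <- brute_force_efms(toy)
    via <- lapply(enumerate_efms_exhaustive(out$network), function(m) {
      flux_mode(decompress(m$v, out$map, toy), toy)
    })
    key <- function(ms) sort(vapply(ms, function(m) {
      v <- normalize_flux(m$v)
      nz <- which(abs(v) > 1e-9)
      if (v[nz[1L]] < 0) v <- -v  # orientation-free signature
      paste(names(v)[nz], sign(v[nz]), collapse = ";")
    }, ""))
    expect_equal(key(via), key(direct), label = paste("seed", seed))
  }
})

test_that("the compression map serializes to JSON", {
  out <- compress(generate_toy_network("diamond"))
  path <- withr::local_tempfile(fileext = ".json")
  write_compression_map(out$map, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_length(back$subsets, length(out$map$subsets))
})
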