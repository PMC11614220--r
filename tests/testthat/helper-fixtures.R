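# shared fixtures, built lazily and cached for the whole test run
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

stroma_net <- function() fixture("stroma_net", synthetic_stroma_model)

stroma_compressed <- function() {
  fixture("stroma_compressed", function() compress(stroma_net()))
}

stroma_cs <- function() {
  fixture("stroma_cs", function() {
    default_constraint_set(stroma_compressed()$network, max_support = 60L)
  })
}

# one shared constrained-EFM sample on the packaged model (the sampler is
# deterministic given the seed, so every test sees the same modes)
stroma_modes <- function() {
  fixture("stroma_modes", function() {
    sample_constrained_efms(stroma_compressed()$network, stroma_cs(),
                            n = 60L, seed = 101L, stall_rounds = 150L,
                            time_limit = 120)
  })
}

support_keys <- function(modes) {
  sort(vapply(modes, function(m) paste(m$support, collapse = ";"), ""))
}

# a toy network with a constrainable branch point: substrate can go to
# product P (reported) or be lost to a side product Q
branched_toy <- function() {
  mets <- rbind(metabolite(c("Sx", "Px", "Qx"), compartment = "external",
                           boundary = TRUE),
                metabolite(c("A", "B", "C")))
  metabolic_network(mets, list(
    reaction("EX_in", c(Sx = -1, A = 1)),
    reaction("TOP", c(A = -1, B = 1)),
    reaction("BOT", c(A = -1, C = 1)),
    reaction("EX_P", c(B = -1, Px = 1)),
    reaction("EX_Q", c(C = -1, Qx = 1), reversible = TRUE)
  ))
}
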