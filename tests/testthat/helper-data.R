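# Small builders shared across tests. Everything is generated in code;
# seeds are fixed so the suite is deterministic.

toy_lineages <- function() {
  list(
    f1 = c("Bacteria", "Firmicutes", "Bacilli"),
    f2 = c("Bacteria", "Firmicutes", "Clostridia"),
    f3 = c("Bacteria", "Bacteroidota", "Bacteroidia")
  )
}

# strictly positive samples x features matrix with unit row sums
rand_composition <- function(n, feats, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rlnorm(n * length(feats)), nrow = n,
                dimnames = list(sprintf("s%03d", seq_len(n)), feats))
    m / rowSums(m)
  })
}

# a small random taxonomy + preprocessed table + labels, optionally with a
# clade-level signal; used by the property-style core tests
rand_instance <- function(seed, n = 80, n_species = 12, ranks = 3,
                          effect = 0, branching = c(2, 3)) {
  spec <- synthetic_spec(n_samples = n, n_species = n_species, ranks = ranks,
                         branching = branching, signal_node_depth = 2,
                         effect_size = effect, sparsity = 0, seed = seed)
  sim <- simulate_dataset(spec)
  values <- add_pseudocount(sim$table$values)
  list(tree = sim$tree, values = values, y = sim$y,
       planted = sim$planted_node)
}
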