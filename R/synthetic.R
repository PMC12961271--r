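# Synthetic lineage-structured abundance data with planted class signal.
#
# The generator emulates a shotgun-metagenomics species table: a rank-
# balanced taxonomy, heavy-tailed (log-normal) within-sample abundances, a
# configurable fraction of structural zeros, and a binary label drawn from a
# logistic model on one clade's standardized aggregated abundance.

#' Specification for a synthetic dataset
#'
#' Defaults describe the study conditions used throughout the package's
#' simulations: 300 samples, 500 species on a 7-rank taxonomy with branching
#' 2-4, signal planted at depth 2 with effect 3 (log-odds per standard
#' deviation of the clade aggregate), log-normal noise with sigma = 2
#' (heavy-tailed, as species abundance distributions are) and 30% zeros.
#'
#' @param n_samples number of samples
#' @param n_species number of species-level features (tree leaves)
#' @param ranks taxonomy depth (number of lineage tokens per species)
#' @param branching integer range `c(lo, hi)` of children per internal node
#'   above the species level
#' @param signal_node_depth depth of the planted-signal node (<= `ranks`;
#'   `ranks` plants the signal on a single species)
#' @param effect_size log-odds of the label per SD of the planted clade's
#'   aggregated abundance
#' @param mu,sigma log-normal parameters of the species abundances
#' @param sparsity fraction of entries zeroed at random, in [0, 1)
#' @param seed integer seed; all generator draws are functions of it
#' @return a `synthetic_spec` list
#' @export
synthetic_spec <- function(n_samples = 300L, n_species = 500L, ranks = 7L,
                           branching = c(2L, 4L), signal_node_depth = 2L,
                           effect_size = 3, mu = 0, sigma = 2,
                           sparsity = 0.3, seed = 1L) {
  stopifnot(n_samples >= 2, n_species >= 1, ranks >= 1,
            length(branching) == 2L, branching[1] >= 1,
            branching[2] >= branching[1],
            signal_node_depth >= 1, signal_node_depth <= ranks,
            is.finite(effect_size), sparsity >= 0, sparsity < 1)
  structure(list(n_samples = as.integer(n_samples),
                 n_species = as.integer(n_species),
                 ranks = as.integer(ranks),
                 branching = as.integer(branching),
                 signal_node_depth = as.integer(signal_node_depth),
                 effect_size = effect_size, mu = mu, sigma = sigma,
                 sparsity = sparsity, seed = as.integer(seed)),
            class = "synthetic_spec")
}

rank_prefix <- function(d, ranks) {
  std <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__", "t__")
  if (ranks <= length(std)) std[d] else paste0("r", d, "_")
}

#' Sample a random rank-balanced taxonomy
#'
#' Species counts are divided as evenly as possible among a per-node number
#' of children drawn from the branching range; the species level absorbs any
#' remaining fan-out. Deterministic under the spec's seed.
#'
#' @param spec a [synthetic_spec()]
#' @return named list of lineages (feature id -> character vector), suitable
#'   for [build_tax_tree()]
#' @export
sample_taxonomy <- function(spec) {
  if (spec$n_species < spec$branching[1] && spec$ranks > 1L) {
    stop("infeasible spec: n_species < minimum branching", call. = FALSE)
  }
  withr::with_seed(spec$seed, {
    counter <- integer(spec$ranks)
    new_name <- function(d) {
      counter[d] <<- counter[d] + 1L
      paste0(rank_prefix(d, spec$ranks), "T", counter[d])
    }
    gen <- function(n, d) {
      if (d == spec$ranks) {
        return(lapply(seq_len(n), function(i) new_name(d)))
      }
      bs <- seq(spec$branching[1], spec$branching[2])
      b <- if (length(bs) == 1L) bs else sample(bs, 1L)
      b <- min(b, n)
      base <- n %/% b
      parts <- rep(base, b)
      extra <- n - base * b
      if (extra > 0L) parts[sample.int(b, extra)] <- base + 1L
      out <- list()
      for (p in parts) {
        nm <- new_name(d)
        sub <- gen(p, d + 1L)
        out <- c(out, lapply(sub, function(tk) c(nm, tk)))
      }
      out
    }
    lins <- gen(spec$n_species, 1L)
    names(lins) <- sprintf("otu%05d", seq_along(lins))
    lins
  })
}

#' Sample species abundances
#'
#' Independent log-normal draws per sample and species, a `sparsity`
#' fraction of entries zeroed at random, and (by default) rows normalized to
#' relative abundances. A sample left all-zero by sparsification is redrawn
#' once; a second failure is an error.
#'
#' @param lineages named lineage list from [sample_taxonomy()]
#' @param spec a [synthetic_spec()]
#' @param normalize return relative abundances (default) or the raw draws
#' @return an `abundance_table`
#' @export
sample_abundances <- function(lineages, spec, normalize = TRUE) {
  withr::with_seed(spec$seed + 1L, {
    n <- spec$n_samples
    s <- length(lineages)
    m <- matrix(rlnorm(n * s, spec$mu, spec$sigma), nrow = n,
                dimnames = list(sprintf("sample%04d", seq_len(n)),
                                names(lineages)))
    if (spec$sparsity > 0) {
      m[matrix(runif(n * s) < spec$sparsity, nrow = n)] <- 0
      dead <- rowSums(m) == 0
      if (any(dead)) {
        for (i in which(dead)) {
          row <- rlnorm(s, spec$mu, spec$sigma)
          row[runif(s) < spec$sparsity] <- 0
          if (sum(row) == 0) {
            stop("sparsity produced an all-zero sample twice; lower it",
                 call. = FALSE)
          }
          m[i, ] <- row
        }
      }
    }
    if (normalize) m <- m / rowSums(m)
    abundance_table(m, lineages)
  })
}

#' Plant a binary class signal on one clade
#'
#' Picks (seeded) one node at the target depth, standardizes its aggregated
#' abundance across samples, and draws labels from
#' `Bernoulli(plogis(effect_size * z))`. The planted node's id is recorded
#' in the `"planted_node"` attribute of the returned vector.
#'
#' @param table an `abundance_table` (relative abundances)
#' @param tree the `tax_tree` built from the table's lineages
#' @param spec a [synthetic_spec()]
#' @return integer 0/1 vector of labels, named by sample id, with
#'   attributes `planted_node` (node id) and `planted_leaves` (feature ids
#'   under the planted node)
#' @export
plant_signal <- function(table, tree, spec) {
  withr::with_seed(spec$seed + 2L, {
    cand <- which(tree$depth == spec$signal_node_depth)
    if (!length(cand)) {
      stop("no node at depth ", spec$signal_node_depth, call. = FALSE)
    }
    node <- cand[sample.int(length(cand), 1L)]
    v <- as_values(table)
    aggv <- rowSums(v[, tree$leaf_ids[[node]], drop = FALSE])
    z <- if (sd(aggv) > 0) (aggv - mean(aggv)) / sd(aggv) else aggv * 0
    y <- rbinom(length(z), 1L, plogis(spec$effect_size * z))
    names(y) <- rownames(v)
    attr(y, "planted_node") <- tree$id[node]
    attr(y, "planted_leaves") <- tree$leaf_ids[[node]]
    y
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper chaining [sample_taxonomy()], [build_tax_tree()],
#' [sample_abundances()] and [plant_signal()].
#'
#' @param spec a [synthetic_spec()]
#' @return list with `table` (an `abundance_table` of relative abundances),
#'   `tree`, `y` (labels), `planted_node`, `planted_leaves` and the `spec`
#' @export
simulate_dataset <- function(spec = synthetic_spec()) {
  lins <- sample_taxonomy(spec)
  tree <- build_tax_tree(lins)
  table <- sample_abundances(lins, spec)
  y <- plant_signal(table, tree, spec)
  list(table = table, tree = tree, y = as.integer(y),
       planted_node = attr(y, "planted_node"),
       planted_leaves = attr(y, "planted_leaves"),
       spec = spec)
}
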