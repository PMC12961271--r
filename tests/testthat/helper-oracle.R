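# Independent reference implementations used as oracles. These deliberately
# share no code with the package: the tree walker is recursive (not a
# queue), the fits come from stats::glm, the BH step-up is hand-coded.

# Brute-force path trie: leaf set of every prefix path, from string
# operations alone.
trie_leafsets <- function(lineages) {
  paths <- lapply(lineages, function(tk) {
    vapply(seq_along(tk), function(k) paste(tk[1:k], collapse = ";"), "")
  })
  all_paths <- unique(unlist(paths))
  sets <- lapply(all_paths, function(p) {
    names(lineages)[vapply(paths, function(pp) p %in% pp, logical(1))]
  })
  names(sets) <- all_paths
  sets
}

brute_filter <- function(v, mean_abundance_min, prevalence_min) {
  keep <- logical(ncol(v))
  for (j in seq_len(ncol(v))) {
    ok_ab <- mean(v[, j]) >= mean_abundance_min
    ok_prev <- (sum(v[, j] > 0) / nrow(v)) >= prevalence_min
    keep[j] <- ok_ab && ok_prev
  }
  keep
}

ref_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Recursive expand-test-every-node-top-down reference for the clade
# selection rules, with all decisions made by stats::glm.
ref_tagine <- function(tree, values, y, alpha = 0.05, start_depth = 1,
                       all_pruned = c("keep_collapsed", "drop_node")) {
  all_pruned <- match.arg(all_pruned)
  agg <- function(i) rowSums(values[, tree$leaf_ids[[i]], drop = FALSE])
  eval_node <- function(i) {
    kids <- tree$children[[i]]
    if (!length(kids)) return(i)
    x0 <- scale(agg(i))
    X <- scale(vapply(kids, agg, numeric(nrow(values))))
    g0 <- suppressWarnings(stats::glm(y ~ x0, family = stats::binomial()))
    g1 <- suppressWarnings(stats::glm(y ~ X, family = stats::binomial()))
    unstable <- !g1$converged || any(abs(stats::coef(g1)[-1]) > 30)
    expand <- !unstable && stats::AIC(g1) < stats::AIC(g0)
    if (!expand) return(i)
    p <- stats::summary.glm(g1)$coefficients[-1, 4]
    keep <- kids[p < alpha]
    if (!length(keep)) {
      return(if (all_pruned == "keep_collapsed") i else integer(0))
    }
    unlist(lapply(keep, eval_node))
  }
  frontier <- match(collapse_to_level(tree, start_depth), tree$id)
  sel <- unlist(lapply(frontier, function(i) {
    if (length(tree$children[[i]])) eval_node(i) else i
  }))
  sort(unique(sel))
}
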