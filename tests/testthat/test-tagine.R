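test_that("a flat tree yields its leaves as features without any model fit", {
  lins <- setNames(lapply(paste0("t", 1:5), identity), paste0("f", 1:5))
  tr <- build_tax_tree(lins)
  v <- rand_composition(30, paste0("f", 1:5), seed = 2)
  y <- rep(c(0, 1), 15)
  fs <- run_tagine(tr, v, y)
  expect_equal(fs$n_comparisons, 0L)
  expect_setequal(fs$features$node_id, tr$id[lengths(tr$children) == 0])
  expect_equal(ncol(fs$matrix), 5L)
})

test_that("preconditions on the table and labels are enforced", {
  tr <- build_tax_tree(toy_lineages())
  v <- rand_composition(10, c("f1", "f2", "f3"), seed = 3)
  y <- rep(c(0, 1), 5)
  expect_error(run_tagine(tr, v, rep(1, 10)), "both classes")
  expect_error(run_tagine(tr, v * 2, y), "sum to 1")
  v0 <- v; v0[1, 1] <- 0; v0[1, ] <- v0[1, ] / sum(v0[1, ])
  expect_error(run_tagine(tr, v0, y), "strictly positive")
})

test_that("a clade-level signal keeps the clade collapsed in most seeds", {
  # two phyla; the label depends only on phylum A's total abundance
  hits <- vapply(1:50, function(s) {
    spec <- synthetic_spec(n_samples = 300, n_species = 40, ranks = 3,
                           branching = c(2, 2), signal_node_depth = 1,
                           effect_size = 2, seed = 4000 + s)
    sim <- simulate_dataset(spec)
    pp <- preprocess(sim$table)
    tree <- build_tax_tree(sim$table$lineages[pp$kept])
    fs <- run_tagine(tree, pp$table, sim$y)
    any(vapply(fs$leaf_ids, function(l) setequal(l, sim$planted_leaves),
               logical(1)))
  }, logical(1))
  expect_gte(mean(hits), 0.70)
})

test_that("a single informative species is reached through repeated expansion", {
  hits <- vapply(1:50, function(s) {
    spec <- synthetic_spec(n_samples = 300, n_species = 8, ranks = 3,
                           branching = c(2, 2), signal_node_depth = 3,
                           effect_size = 2.5, seed = 5000 + s)
    sim <- simulate_dataset(spec)
    pp <- preprocess(sim$table)
    tree <- build_tax_tree(sim$table$lineages[pp$kept])
    fs <- run_tagine(tree, pp$table, sim$y)
    any(vapply(fs$leaf_ids, function(l) setequal(l, sim$planted_leaves),
               logical(1)))
  }, logical(1))
  expect_gte(mean(hits), 0.80)
})

test_that("selected features never nest and their columns match the aggregation", {
  for (s in 1:20) {
    inst <- rand_instance(6000 + s, effect = (s %% 3) * 1.5)
    fs <- run_tagine(inst$tree, inst$values, inst$y)
    sets <- fs$leaf_ids
    if (length(sets) >= 2) {
      for (i in seq_along(sets)[-1]) {
        for (j in seq_len(i - 1)) {
          expect_length(intersect(sets[[i]], sets[[j]]), 0)
        }
      }
    }
    ag <- aggregate_abundances(inst$tree, inst$values)
    expect_lt(max(abs(fs$matrix - ag[, fs$features$node_id, drop = FALSE])),
              1e-12)
  }
})

test_that("runs are deterministic and queue-order independent", {
  inst <- rand_instance(7001, effect = 2)
  fs1 <- run_tagine(inst$tree, inst$values, inst$y)
  fs2 <- run_tagine(inst$tree, inst$values, inst$y)
  expect_identical(fs1, fs2)

  for (s in 1:50) {
    inst <- rand_instance(7100 + s, effect = (s %% 4))
    fifo <- run_tagine(inst$tree, inst$values, inst$y,
                       tagine_config(queue = "fifo"))
    lifo <- run_tagine(inst$tree, inst$values, inst$y,
                       tagine_config(queue = "lifo"))
    expect_setequal(fifo$features$node_id, lifo$features$node_id)
  }
})

test_that("each internal node is examined at most once", {
  for (s in 1:10) {
    inst <- rand_instance(7500 + s, n_species = 30, ranks = 4, effect = 2)
    fs <- run_tagine(inst$tree, inst$values, inst$y)
    n_internal <- sum(lengths(inst$tree$children) > 0)
    expect_lte(fs$n_comparisons, n_internal)
    # and the audit trail never revisits a node
    ids <- vapply(fs$decisions, `[[`, "", "node_id")
    expect_false(anyDuplicated(ids) > 0)
  }
})

test_that("pruning the tree leaves exactly the selected features as leaves", {
  # nothing expands under pure-noise labels at a tiny alpha: the pruned tree
  # is the root plus the starting frontier
  inst <- rand_instance(7777, effect = 0)
  fs <- run_tagine(inst$tree, inst$values, inst$y)
  pt <- prune_tree(inst$tree, fs)
  expect_setequal(pt$id[lengths(pt$children) == 0], fs$features$node_id)

  # with signal: still exactly the features, at mixed depths
  inst2 <- rand_instance(7778, n_species = 20, effect = 3)
  fs2 <- run_tagine(inst2$tree, inst2$values, inst2$y)
  pt2 <- prune_tree(inst2$tree, fs2)
  expect_setequal(pt2$id[lengths(pt2$children) == 0], fs2$features$node_id)
  # ancestors are preserved: every feature is reachable from the root
  expect_true(all(!is.na(pt2$parent[-pt2$root])))
})

test_that("transform reproduces training columns and maps new samples", {
  inst <- rand_instance(8001, n_species = 20, effect = 2)
  fs <- run_tagine(inst$tree, inst$values, inst$y)
  expect_equal(tagine_transform(inst$values, fs), fs$matrix, tolerance = 1e-12)

  z <- matrix(0, nrow = 1, ncol = ncol(inst$values),
              dimnames = list("new", colnames(inst$values)))
  expect_true(all(tagine_transform(z, fs) == 0))

  bad <- inst$values[, -1, drop = FALSE]
  needed <- unique(unlist(fs$leaf_ids))
  if (colnames(inst$values)[1] %in% needed) {
    expect_error(tagine_transform(bad, fs), "lacks")
  }
})

test_that("run outputs can be written and read back", {
  inst <- rand_instance(8101, n_species = 15, effect = 2)
  fs <- run_tagine(inst$tree, inst$values, inst$y)
  dir <- withr::local_tempdir()
  write_tagine_outputs(fs, inst$tree, dir)
  expect_true(file.exists(file.path(dir, "features.tsv")))
  feats <- read.delim(file.path(dir, "features.tsv"), check.names = FALSE)
  expect_equal(nrow(feats), nrow(fs$features))
  nwk <- readLines(file.path(dir, "pruned_tree.nwk"))
  expect_match(nwk, ";$")
  dec <- jsonlite::read_json(file.path(dir, "decisions.json"))
  expect_length(dec$decisions, fs$n_comparisons)
})
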