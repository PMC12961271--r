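# The TAGINE loop: seed a queue with the collapsed starting frontier, pop
# nodes one at a time, decide expand-vs-keep by the AIC comparison, Wald-
# prune non-significant children, and emit the remaining leaves of the
# pruned tree as the final feature set.

#' Configuration for a TAGINE run
#'
#' @param start_depth depth of the starting frontier (1 = one level below
#'   the artificial root, the default)
#' @param alpha Wald significance level used to prune children of expanded
#'   nodes (default 0.05)
#' @param use_log_abundance fit regressions on log abundances (safe after
#'   pseudocounting) instead of the raw relative abundances
#' @param on_all_children_pruned what to do when a node is expanded but
#'   every child is Wald-pruned: `"keep_collapsed"` (default) retains the
#'   node itself as a feature — the AIC verdict established that the clade
#'   carries signal even if individual child coefficients are unstable —
#'   while `"drop_node"` removes the clade entirely
#' @param queue `"fifo"` (default) or `"lifo"`; the final feature set does
#'   not depend on the order, only the audit log's readability does
#' @return a `tagine_config` list
#' @export
tagine_config <- function(start_depth = 1L, alpha = 0.05,
                          use_log_abundance = FALSE,
                          on_all_children_pruned = c("keep_collapsed",
                                                     "drop_node"),
                          queue = c("fifo", "lifo")) {
  start_depth <- as.integer(start_depth)
  if (is.na(start_depth) || start_depth < 1L) {
    stop("`start_depth` must be >= 1", call. = FALSE)
  }
  if (alpha <= 0 || alpha > 1) stop("`alpha` must be in (0, 1]", call. = FALSE)
  structure(list(start_depth = start_depth, alpha = alpha,
                 use_log_abundance = isTRUE(use_log_abundance),
                 on_all_children_pruned = match.arg(on_all_children_pruned),
                 tie_rule = "keep_collapsed",
                 queue = match.arg(queue)),
            class = "tagine_config")
}

#' Run the TAGINE algorithm
#'
#' Seeds a queue with the tree collapsed to `config$start_depth`, then
#' iteratively pops a node and compares, by AIC, a logistic regression on
#' the node's aggregated abundance against one on its children's abundances.
#' A node that does not improve by expansion stays collapsed and becomes a
#' final feature (its descendants are never examined). When a node is
#' expanded, children with non-significant Wald coefficients are pruned from
#' the tree and never enqueued; surviving internal children are enqueued and
#' surviving leaf children become final features. The algorithm ends when
#' the queue is empty; each internal node is examined at most once.
#'
#' @param tree a `tax_tree` whose leaves are exactly the table's features
#' @param values preprocessed samples x features matrix: strictly positive,
#'   rows summing to 1 (see [preprocess()])
#' @param y binary 0/1 labels, one per sample, both classes present
#' @param config a [tagine_config()]
#' @return an object of class `tagine_features`: `features` (data frame of
#'   node id, display name, rank depth, leaf count), `matrix` (samples x
#'   selected features aggregated abundances), `leaf_ids` (features'
#'   training-time leaf sets, used by [tagine_transform()]), `decisions`
#'   (one audit record per examined internal node), `pruned_node_ids`,
#'   `n_comparisons`, and the `config`
#' @export
run_tagine <- function(tree, values, y, config = tagine_config()) {
  values <- as_values(values)
  y <- as.numeric(y)
  check_tree_features(tree, values)
  if (nrow(values) != length(y)) stop("nrow(values) != length(y)", call. = FALSE)
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2L) {
    stop("`y` must be binary 0/1 with both classes present", call. = FALSE)
  }
  if (any(values <= 0)) {
    stop("`values` must be strictly positive; run preprocess() first",
         call. = FALSE)
  }
  if (max(abs(rowSums(values) - 1)) > 1e-6) {
    stop("sample rows must sum to 1; run preprocess() first", call. = FALSE)
  }

  col_of <- match(tree$feature, colnames(values))  # NA for internal nodes
  leaf_cols <- lapply(tree$leaf_ids, function(f) match(f, colnames(values)))
  agg <- function(i) rowSums(values[, leaf_cols[[i]], drop = FALSE])

  frontier_ids <- collapse_to_level(tree, config$start_depth)
  queue <- match(frontier_ids, tree$id)
  selected <- integer(0)
  pruned <- integer(0)
  decisions <- list()

  while (length(queue)) {
    if (config$queue == "fifo") {
      node <- queue[1L]; queue <- queue[-1L]
    } else {
      node <- queue[length(queue)]; queue <- queue[-length(queue)]
    }
    kids <- tree$children[[node]]
    if (length(kids) == 0L) {           # popped leaf: emit directly
      selected <- c(selected, node)
      next
    }
    node_ab <- agg(node)
    child_ab <- vapply(kids, agg, numeric(nrow(values)))
    if (nrow(values) == 1L) child_ab <- matrix(child_ab, nrow = 1L)
    colnames(child_ab) <- tree$id[kids]
    cmp <- compare_models(node_ab, child_ab, y, alpha = config$alpha,
                          use_log = config$use_log_abundance,
                          check_sum = FALSE)
    decision <- list(node_id = tree$id[node],
                     n_children = length(kids),
                     aic_collapsed = cmp$aic_collapsed,
                     aic_expanded = cmp$aic_expanded,
                     expanded = cmp$expand,
                     pruned_children = character(0),
                     fallback_reason = cmp$fallback_reason)
    if (!cmp$expand) {
      selected <- c(selected, node)
    } else {
      keep <- kids[cmp$significant_children]
      drop <- kids[!cmp$significant_children]
      decision$pruned_children <- tree$id[drop]
      pruned <- c(pruned, drop)
      if (length(keep) == 0L) {
        if (config$on_all_children_pruned == "keep_collapsed") {
          decision$expanded <- FALSE
          decision$fallback_reason <- "all children pruned; kept collapsed"
          selected <- c(selected, node)
          pruned <- setdiff(pruned, drop)
          decision$pruned_children <- character(0)
        }
        # drop_node: clade disappears entirely
      } else {
        for (k in keep) {
          if (length(tree$children[[k]]) == 0L) {
            selected <- c(selected, k)
          } else {
            queue <- c(queue, k)
          }
        }
      }
    }
    decisions[[length(decisions) + 1L]] <- decision
  }

  selected <- selected[order(selected)]  # preorder: deterministic output
  if (length(selected) == 0L) {
    warning("every feature was pruned; returning an empty feature set",
            call. = FALSE)
    mat <- matrix(numeric(0), nrow = nrow(values), ncol = 0,
                  dimnames = list(rownames(values), character(0)))
    feats <- data.frame(node_id = character(0), name = character(0),
                        rank_depth = integer(0), n_leaves = integer(0),
                        stringsAsFactors = FALSE)
    lids <- setNames(list(), character(0))
  } else {
    mat <- vapply(selected, agg, numeric(nrow(values)))
    if (nrow(values) == 1L) mat <- matrix(mat, nrow = 1L)
    dimnames(mat) <- list(rownames(values), tree$id[selected])
    feats <- data.frame(node_id = tree$id[selected],
                        name = tree$name[selected],
                        rank_depth = tree$depth[selected],
                        n_leaves = lengths(tree$leaf_ids[selected]),
                        stringsAsFactors = FALSE)
    lids <- setNames(tree$leaf_ids[selected], tree$id[selected])
  }
  structure(list(features = feats, matrix = mat, leaf_ids = lids,
                 decisions = decisions,
                 pruned_node_ids = tree$id[unique(pruned)],
                 n_comparisons = length(decisions),
                 config = config),
            class = "tagine_features")
}

#' @export
print.tagine_features <- function(x, ...) {
  cat("<tagine_features> ", nrow(x$features), " selected clades (",
      x$n_comparisons, " node comparisons)\n", sep = "")
  if (nrow(x$features)) {
    tab <- table(x$features$rank_depth)
    cat("  by depth: ",
        paste(sprintf("d%s:%d", names(tab), as.integer(tab)), collapse = " "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Prune a tree down to a run's selected clades
#'
#' Returns the tree restricted to the selected features and their ancestors:
#' descendants of unexpanded nodes and Wald-pruned subtrees are removed, so
#' the leaves of the result are exactly the run's features (which may
#' include collapsed internal nodes of the input tree).
#'
#' @param tree the `tax_tree` the run was made on
#' @param result a `tagine_features` object from [run_tagine()]
#' @return a `tax_tree` whose leaves are the selected features
#' @export
prune_tree <- function(tree, result) {
  sel <- match(result$features$node_id, tree$id)
  if (anyNA(sel)) stop("result does not belong to this tree", call. = FALSE)
  keep <- sort(unique(unlist(lapply(sel, node_ancestry, tree = tree))))
  if (length(keep) == 0L) keep <- tree$root
  remap <- match(seq_along(tree$id), keep)  # old index -> new index
  sel_new <- remap[sel]
  children <- lapply(tree$children[keep], function(k) {
    k2 <- remap[k]
    k2[!is.na(k2)]
  })
  # selected nodes are leaves of the pruned tree
  children[stats::na.omit(sel_new)] <- list(integer(0))
  feature <- tree$feature[keep]
  feature[sel_new] <- tree$id[sel]  # selected clades act as features now
  structure(list(
    name = tree$name[keep],
    parent = remap[tree$parent[keep]],
    depth = tree$depth[keep],
    feature = feature,
    id = tree$id[keep],
    children = children,
    leaf_ids = tree$leaf_ids[keep],
    root = 1L,
    n_leaves = length(sel)
  ), class = "tax_tree")
}

#' Apply a learned feature set to new samples
#'
#' Each output column is the sum of the new samples' abundances over the
#' leaf features captured for that clade at training time. Leaves that were
#' Wald-pruned during training belong to no feature: their abundance is
#' excluded, not re-added elsewhere.
#'
#' @param values samples x features matrix (or `abundance_table`) over the
#'   same features the training tree was built on
#' @param result a `tagine_features` object
#' @return samples x selected-features matrix
#' @export
tagine_transform <- function(values, result) {
  values <- as_values(values)
  needed <- unique(unlist(result$leaf_ids, use.names = FALSE))
  miss <- setdiff(needed, colnames(values))
  if (length(miss)) {
    stop("new table lacks feature(s): ",
         paste(head(miss, 10L), collapse = ", "), call. = FALSE)
  }
  out <- vapply(result$leaf_ids, function(f) {
    rowSums(values[, f, drop = FALSE])
  }, numeric(nrow(values)))
  if (nrow(values) == 1L) out <- matrix(out, nrow = 1L)
  dimnames(out) <- list(rownames(values), names(result$leaf_ids))
  out
}

#' Write the outputs of a TAGINE run to a directory
#'
#' Emits `features.tsv` (selected features x samples, with the taxonomic
#' path), `pruned_tree.nwk` (Newick) and `decisions.json` (per-node audit
#' records plus the configuration and, when given, the filter report).
#'
#' @param result a `tagine_features` object
#' @param tree the `tax_tree` of the run
#' @param dir output directory (created if needed)
#' @param filter_report optional `filter_report` to embed in the JSON
#' @return `dir`, invisibly
#' @export
write_tagine_outputs <- function(result, tree, dir, filter_report = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- data.frame(feature = result$features$node_id,
                    taxonomic_path = result$features$node_id,
                    rank_depth = result$features$rank_depth,
                    t(result$matrix), check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(tab, file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_newick(prune_tree(tree, result), file.path(dir, "pruned_tree.nwk"))
  payload <- list(config = unclass(result$config),
                  n_comparisons = result$n_comparisons,
                  pruned_node_ids = result$pruned_node_ids,
                  decisions = result$decisions)
  if (!is.null(filter_report)) payload$filter_report <- unclass(filter_report)
  jsonlite::write_json(payload, file.path(dir, "decisions.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(dir)
}
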