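# Rank-based taxonomic trees built from lineage strings.
#
# A tax_tree is a flat, index-addressed structure (parallel vectors plus a
# children list), which keeps traversal cheap for taxonomies with thousands
# of leaves. Node ids are the full path of display names from the root,
# joined by ";", so an ancestor's id is always a prefix of its descendants'.

ROOT_NAME <- "Root"

#' Build a taxonomic tree from lineages
#'
#' Constructs a rooted, rank-based tree whose leaves are exactly the supplied
#' features. An artificial root is always added above the top rank, so the
#' conventional starting frontier "one level below the root" is well defined
#' even for single-kingdom datasets. Single-child chains (which arise from
#' unassigned intermediate ranks) are compressed at build time: the chain is
#' merged into one node whose display name concatenates the chain with `"|"`,
#' so that every decision node has at least two children. Unassigned tokens
#' (`"g__"`, `"NA"`, ...) are ordinary names scoped under their parent; two
#' identical placeholder names under different parents are different nodes.
#'
#' @param lineages named list; one character vector of taxon names per
#'   feature, ordered from the highest rank down. Names are the feature ids.
#' @return An object of class `tax_tree` with elements `name`, `parent`,
#'   `children`, `depth` (root = 0), `feature` (feature id for leaves, `NA`
#'   otherwise), `leaf_ids` (feature ids under each node), `id` (stable
#'   path-based node ids), `root`, `n_leaves`.
#' @examples
#' tr <- build_tax_tree(list(
#'   f1 = c("Bacteria", "Firmicutes", "Bacilli"),
#'   f2 = c("Bacteria", "Firmicutes", "Clostridia"),
#'   f3 = c("Bacteria", "Bacteroidota", "Bacteroidia")
#' ))
#' tr$n_leaves
#' @export
build_tax_tree <- function(lineages) {
  if (length(lineages) == 0L) {
    stop("`lineages` is empty: at least one feature is required", call. = FALSE)
  }
  ids <- names(lineages)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids))) {
    stop("`lineages` must be a named list keyed by feature id", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate feature ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  lineages <- lapply(lineages, function(x) trimws(as.character(x)))
  if (any(lengths(lineages) == 0L)) {
    bad <- ids[lengths(lineages) == 0L]
    stop("empty lineage for feature(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  # Recursive trie construction; detects conflicting lineages on the way.
  build_node <- function(name, feat_ids, toks, path) {
    ended <- lengths(toks) == 0L
    if (any(ended)) {
      if (length(feat_ids) > 1L) {
        offenders <- feat_ids[order(!ended)]
        stop("conflicting lineages at path '", path, "': features ",
             paste(offenders, collapse = ", "),
             " claim a leaf at or below the same position", call. = FALSE)
      }
      return(list(name = name, feature = feat_ids, children = list()))
    }
    first <- vapply(toks, `[[`, character(1), 1L)
    rest <- lapply(toks, `[`, -1L)
    kids <- lapply(sort(unique(first)), function(tok) {
      sel <- first == tok
      build_node(tok, feat_ids[sel], rest[sel],
                 if (nzchar(path)) paste(path, tok, sep = ";") else tok)
    })
    list(name = name, feature = NA_character_, children = kids)
  }
  root <- build_node(ROOT_NAME, ids, lineages, "")

  # Chain compression (top-down). The root absorbs a single internal child;
  # an internal non-root node with a single child merges with it (becoming a
  # leaf when the child is one). A single leaf child of the root is kept.
  compress <- function(node, is_root) {
    repeat {
      if (length(node$children) != 1L) break
      ch <- node$children[[1L]]
      if (is.na(ch$feature)) {
        node$name <- paste(node$name, ch$name, sep = "|")
        node$children <- ch$children
      } else if (!is_root) {
        node$name <- paste(node$name, ch$name, sep = "|")
        node$feature <- ch$feature
        node$children <- list()
        break
      } else {
        break
      }
    }
    node$children <- lapply(node$children, compress, is_root = FALSE)
    # keep deterministic lexicographic child order after compression
    if (length(node$children) > 1L) {
      ord <- order(vapply(node$children, `[[`, character(1), "name"),
                   method = "radix")
      node$children <- node$children[ord]
    }
    node
  }
  root <- compress(root, is_root = TRUE)

  # Flatten to parallel vectors (preorder).
  n_est <- 2L * length(ids) + 2L
  name <- character(n_est); parent <- integer(n_est); depth <- integer(n_est)
  feature <- character(n_est); id <- character(n_est)
  children <- vector("list", n_est); leaf_ids <- vector("list", n_est)
  nxt <- 0L
  rec <- function(node, parent_idx, d, parent_id) {
    nxt <<- nxt + 1L
    i <- nxt
    name[i] <<- node$name
    parent[i] <<- parent_idx
    depth[i] <<- d
    feature[i] <<- node$feature
    id[i] <<- if (is.na(parent_idx)) node$name else
      paste(parent_id, node$name, sep = ";")
    my_id <- id[i]
    if (length(node$children) == 0L) {
      children[[i]] <<- integer(0)
      leaf_ids[[i]] <<- node$feature
    } else {
      kid_idx <- vapply(node$children, function(ch) {
        rec(ch, i, d + 1L, my_id)
      }, integer(1))
      children[[i]] <<- kid_idx
      leaf_ids[[i]] <<- unlist(leaf_ids[kid_idx], use.names = FALSE)
    }
    i
  }
  rec(root, NA_integer_, 0L, "")
  keep <- seq_len(nxt)

  tree <- structure(list(
    name = name[keep], parent = parent[keep], depth = depth[keep],
    feature = feature[keep], id = id[keep],
    children = children[keep], leaf_ids = leaf_ids[keep],
    root = 1L, n_leaves = length(ids)
  ), class = "tax_tree")
  tree
}

#' @export
print.tax_tree <- function(x, ...) {
  n_int <- sum(lengths(x$children) > 0L)
  cat("<tax_tree> ", x$n_leaves, " leaves, ", n_int, " internal nodes, depth ",
      max(x$depth), "\n", sep = "")
  invisible(x)
}

is_leaf <- function(tree) lengths(tree$children) == 0L

#' Leaf feature ids of a tree
#' @param tree a `tax_tree`
#' @return character vector of feature ids (one per leaf)
#' @export
tree_leaves <- function(tree) {
  tree$feature[is_leaf(tree)]
}

#' Read lineages back out of a tree
#'
#' Returns, for every leaf, the display names along its path below the root.
#' Rebuilding a tree from this list reproduces an isomorphic tree (chain
#' compression is idempotent).
#' @param tree a `tax_tree`
#' @return named list of character vectors keyed by feature id
#' @export
tree_lineages <- function(tree) {
  leaves <- which(is_leaf(tree))
  out <- lapply(leaves, function(i) {
    path <- character(0)
    while (!is.na(tree$parent[i])) {
      path <- c(tree$name[i], path)
      i <- tree$parent[i]
    }
    path
  })
  names(out) <- tree$feature[leaves]
  out
}

#' Aggregate leaf abundances to every node
#'
#' Internal-node abundances are the sum of their children's abundances;
#' equivalently, the sum of the original features under the node. Leaf values
#' are copied unchanged.
#'
#' @param tree a `tax_tree`
#' @param values samples x features numeric matrix whose column names are
#'   exactly the tree's leaf feature ids
#' @return samples x nodes matrix, columns named by node id (preorder)
#' @export
aggregate_abundances <- function(tree, values) {
  check_tree_features(tree, values)
  out <- vapply(seq_along(tree$id), function(i) {
    rowSums(values[, tree$leaf_ids[[i]], drop = FALSE])
  }, numeric(nrow(values)))
  if (nrow(values) == 1L) out <- matrix(out, nrow = 1L)
  dimnames(out) <- list(rownames(values), tree$id)
  out
}

check_tree_features <- function(tree, values) {
  feats <- colnames(values)
  leaves <- tree_leaves(tree)
  if (is.null(feats)) stop("abundance matrix must have feature column names",
                           call. = FALSE)
  extra <- setdiff(feats, leaves)
  missing <- setdiff(leaves, feats)
  if (length(extra) || length(missing)) {
    stop("feature/leaf mismatch; in table but not tree: [",
         paste(head(extra, 10L), collapse = ", "),
         "]; in tree but not table: [",
         paste(head(missing, 10L), collapse = ", "), "]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Collapse a tree to a starting level
#'
#' Returns the frontier used to seed the algorithm's queue: every node at
#' `rank_depth == depth` plus any leaf shallower than `depth`. The frontier's
#' leaf sets partition all leaves. A `depth` beyond the deepest node simply
#' returns all leaves.
#'
#' @param tree a `tax_tree`
#' @param depth integer >= 1; depth 1 is one level below the (artificial) root
#' @return character vector of node ids, in preorder
#' @export
collapse_to_level <- function(tree, depth) {
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 1L) {
    stop("`depth` must be an integer >= 1", call. = FALSE)
  }
  sel <- tree$depth == depth | (is_leaf(tree) & tree$depth < depth)
  tree$id[sel]
}

#' Write a tree in Newick format
#'
#' Labels are single-quoted (display names of compressed chains contain
#' `"|"`); branch lengths are omitted.
#'
#' @param tree a `tax_tree`
#' @param path optional file path; when `NULL` the string is returned only
#' @return the Newick string, invisibly when written to a file
#' @export
write_newick <- function(tree, path = NULL) {
  quote_lab <- function(x) paste0("'", gsub("'", "''", x, fixed = TRUE), "'")
  rec <- function(i) {
    if (length(tree$children[[i]]) == 0L) return(quote_lab(tree$name[i]))
    paste0("(", paste(vapply(tree$children[[i]], rec, character(1)),
                      collapse = ","), ")", quote_lab(tree$name[i]))
  }
  nwk <- paste0(rec(tree$root), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

# Indices of node i and all its ancestors up to the root.
node_ancestry <- function(tree, i) {
  out <- i
  while (!is.na(tree$parent[i])) {
    i <- tree$parent[i]
    out <- c(out, i)
  }
  out
}
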