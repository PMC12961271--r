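# Benchmarking protocol: repeated stratified train/test splits, random-
# forest AUC-ROC on each engineered feature set, and paired comparisons via
# the Nadeau-Bengio corrected resampled t-test with BH FDR control.

#' Repeated stratified train/test splits
#'
#' Class-stratified random partitions; the training size is `round(n *
#' train_fraction)` with per-class allocation by largest remainder, clamped
#' so both classes appear in both halves.
#'
#' @param sample_ids character vector of sample ids
#' @param labels binary 0/1 labels aligned with `sample_ids`
#' @param n_repeats number of repeats (default 50)
#' @param train_fraction fraction of samples used for training (default 0.85)
#' @param seed integer seed
#' @return an object of class `split_plan`: list with `n_repeats`,
#'   `train_fraction`, `seed` and `assignments` (per repeat, a list with
#'   `train` and `test` id vectors)
#' @export
make_splits <- function(sample_ids, labels, n_repeats = 50L,
                        train_fraction = 0.85, seed = 1L) {
  stopifnot(length(sample_ids) == length(labels), n_repeats >= 1,
            train_fraction > 0, train_fraction < 1)
  labels <- as.integer(labels)
  n_by <- table(factor(labels, levels = c(0L, 1L)))
  if (any(n_by < 2L)) {
    stop("need at least 2 samples per class to split", call. = FALSE)
  }
  n <- length(sample_ids)
  n_train <- round(n * train_fraction)
  # largest-remainder allocation of the train quota across classes
  exact <- as.numeric(n_by) * train_fraction
  alloc <- floor(exact)
  rem <- n_train - sum(alloc)
  if (rem > 0) {
    ord <- order(exact - alloc, decreasing = TRUE)
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1L
  }
  alloc <- pmin(pmax(alloc, 1L), as.numeric(n_by) - 1L)
  withr::with_seed(seed, {
    assignments <- lapply(seq_len(n_repeats), function(r) {
      train <- unlist(lapply(c(0L, 1L), function(cl) {
        ids <- sample_ids[labels == cl]
        sample(ids, alloc[cl + 1L])
      }), use.names = FALSE)
      list(train = train, test = setdiff(sample_ids, train))
    })
    structure(list(n_repeats = as.integer(n_repeats),
                   train_fraction = train_fraction, seed = as.integer(seed),
                   assignments = assignments),
              class = "split_plan")
  })
}

#' Rank-based AUC-ROC
#'
#' Mann-Whitney construction: the probability that a random positive scores
#' higher than a random negative, with ties counted half.
#'
#' @param scores numeric prediction scores
#' @param labels binary 0/1 labels
#' @return AUC in [0, 1]
#' @export
auc_roc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Nadeau-Bengio corrected resampled t-test
#'
#' Paired two-sided test on per-split differences from J overlapping random
#' train/test splits. The naive variance term 1/J is inflated to
#' `1/J + n_test/n_train` to account for the dependence between splits:
#' `t = mean(d) / sqrt((1/J + n_test/n_train) * var(d))`, compared against a
#' Student t with J - 1 degrees of freedom. As `n_test/n_train -> 0` this
#' reduces to the classical one-sample t-test.
#'
#' @param diffs per-split metric differences (length J >= 2)
#' @param n_train,n_test split sizes
#' @return list with `t`, `p` (two-sided), `df`
#' @export
nb_corrected_ttest <- function(diffs, n_train, n_test) {
  J <- length(diffs)
  if (J < 2L) stop("need at least 2 differences", call. = FALSE)
  v <- var(diffs)
  m <- mean(diffs)
  if (v == 0) {
    if (m == 0) return(list(t = 0, p = 1, df = J - 1L))
    warning("zero variance with nonzero mean difference", call. = FALSE)
    return(list(t = sign(m) * Inf, p = 0, df = J - 1L))
  }
  t_stat <- m / sqrt((1 / J + n_test / n_train) * v)
  list(t = t_stat, p = 2 * pt(-abs(t_stat), df = J - 1L), df = J - 1L)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment (delegates to `stats::p.adjust`).
#'
#' @param pvalues numeric vector in [0, 1]
#' @return q-values, same length and order
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvalues, method = "BH")
}

parse_method <- function(m) {
  if (startsWith(m, "fixed-level:")) {
    list(kind = "fixed-level",
         depth = as.integer(sub("^fixed-level:", "", m)))
  } else {
    list(kind = m, depth = NA_integer_)
  }
}

#' Benchmark feature-engineering methods on repeated splits
#'
#' For every repeat: preprocessing statistics (rarity filter) are computed
#' on the training samples only; each method engineers features from the
#' training data; held-out samples are mapped through the same features; a
#' random forest (ranger, 500 trees, per-repeat seed, one thread) is trained
#' and its held-out AUC-ROC recorded together with the feature count and,
#' for TAGINE, the number of node comparisons. Methods are compared pairwise
#' on the paired per-repeat AUC differences with [nb_corrected_ttest()] and
#' [bh_fdr()].
#'
#' @param table an `abundance_table` with lineages (raw or relative
#'   abundances)
#' @param y binary 0/1 labels aligned with the table's samples
#' @param methods character vector; supported: `"tagine"`, `"none"` (no
#'   selection), `"all-levels"` (every tree node as a feature),
#'   `"fixed-level:<depth>"` (collapse at a fixed rank depth)
#' @param n_repeats,train_fraction,seed passed to [make_splits()]
#' @param config a [tagine_config()] for the TAGINE runs
#' @param num_trees random-forest size (default 500)
#' @param mean_abundance_min,prevalence_min rarity-filter thresholds
#' @return an object of class `benchmark_result`: `results` (data frame
#'   with one row per repeat x method: `auc`, `n_features`, `fit_count`),
#'   `comparisons` (pairwise `t`, `p_value`, `q_value`), and the `plan`
#' @export
benchmark_methods <- function(table, y, methods = c("tagine", "none"),
                              n_repeats = 20L, train_fraction = 0.85,
                              seed = 1L, config = tagine_config(),
                              num_trees = 500L,
                              mean_abundance_min = 1e-6,
                              prevalence_min = 1e-2) {
  stopifnot(inherits(table, "abundance_table"), !is.null(table$lineages),
            length(methods) >= 1)
  v <- table$values
  y <- as.integer(y)
  plan <- make_splits(rownames(v), y, n_repeats = n_repeats,
                      train_fraction = train_fraction, seed = seed)
  names(y) <- rownames(v)

  rows <- list()
  for (r in seq_len(plan$n_repeats)) {
    a <- plan$assignments[[r]]
    ytr <- y[a$train]; yte <- y[a$test]
    pp <- preprocess(v[a$train, , drop = FALSE],
                     mean_abundance_min = mean_abundance_min,
                     prevalence_min = prevalence_min)
    Xtr <- pp$table
    te_raw <- v[a$test, pp$kept, drop = FALSE]
    dead <- rowSums(te_raw) == 0  # held-out sample empty on kept features
    if (any(dead)) te_raw[dead, ] <- 1 / ncol(te_raw)
    Xte <- add_pseudocount(normalize_relative(te_raw))
    tree <- build_tax_tree(table$lineages[pp$kept])

    for (m in methods) {
      pm <- parse_method(m)
      fit_count <- 0L
      if (pm$kind == "tagine") {
        fs <- run_tagine(tree, Xtr, ytr, config)
        if (nrow(fs$features) == 0L) {
          rows[[length(rows) + 1L]] <- data.frame(
            rep = r, method = m, auc = NA_real_, n_features = 0L,
            fit_count = fs$n_comparisons, stringsAsFactors = FALSE)
          next
        }
        Ftr <- fs$matrix
        Fte <- tagine_transform(Xte, fs)
        fit_count <- fs$n_comparisons
      } else if (pm$kind == "none") {
        Ftr <- Xtr; Fte <- Xte
      } else if (pm$kind == "all-levels") {
        Ftr <- aggregate_abundances(tree, Xtr)
        Fte <- aggregate_abundances(tree, Xte)
      } else if (pm$kind == "fixed-level") {
        ids <- collapse_to_level(tree, pm$depth)
        idx <- match(ids, tree$id)
        Ftr <- vapply(idx, function(i)
          rowSums(Xtr[, tree$leaf_ids[[i]], drop = FALSE]),
          numeric(nrow(Xtr)))
        Fte <- vapply(idx, function(i)
          rowSums(Xte[, tree$leaf_ids[[i]], drop = FALSE]),
          numeric(nrow(Xte)))
        colnames(Ftr) <- colnames(Fte) <- ids
      } else {
        stop("unknown method: ", m, call. = FALSE)
      }
      auc <- rf_auc(Ftr, ytr, Fte, yte,
                    num_trees = num_trees, seed = seed + 1000L * r)
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, method = m, auc = auc, n_features = ncol(Ftr),
        fit_count = fit_count, stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)

  comparisons <- NULL
  if (length(methods) >= 2L) {
    n_tr <- length(plan$assignments[[1L]]$train)
    n_te <- length(plan$assignments[[1L]]$test)
    prs <- combn(methods, 2L)
    comp_rows <- lapply(seq_len(ncol(prs)), function(k) {
      m1 <- prs[1L, k]; m2 <- prs[2L, k]
      a1 <- results$auc[results$method == m1]
      a2 <- results$auc[results$method == m2]
      ok <- !is.na(a1) & !is.na(a2)
      if (sum(ok) < length(a1)) {
        warning("excluding ", sum(!ok), " repeat(s) with missing AUC for ",
                m1, " vs ", m2, call. = FALSE)
      }
      tt <- nb_corrected_ttest(a1[ok] - a2[ok], n_tr, n_te)
      data.frame(method_a = m1, method_b = m2,
                 mean_diff = mean(a1[ok] - a2[ok]),
                 t_statistic = tt$t, p_value = tt$p,
                 stringsAsFactors = FALSE)
    })
    comparisons <- do.call(rbind, comp_rows)
    comparisons$q_value <- bh_fdr(comparisons$p_value)
  }
  structure(list(results = results, comparisons = comparisons, plan = plan),
            class = "benchmark_result")
}

rf_auc <- function(Xtr, ytr, Xte, yte, num_trees = 500L, seed = 1L) {
  # ranger matches columns by name at prediction; use syntactic names
  cn <- paste0("f", seq_len(ncol(Xtr)))
  dtr <- as.data.frame(Xtr); colnames(dtr) <- cn
  dte <- as.data.frame(Xte); colnames(dte) <- cn
  fit <- ranger::ranger(x = dtr, y = factor(ytr, levels = c(0L, 1L)),
                        probability = TRUE, num.trees = num_trees,
                        seed = seed %% .Machine$integer.max,
                        num.threads = 1L)
  pr <- stats::predict(fit, data = dte)$predictions[, "1"]
  auc_roc(pr, yte)
}

#' @export
print.benchmark_result <- function(x, ...) {
  agg <- stats::aggregate(cbind(auc, n_features) ~ method, data = x$results,
                          FUN = mean, na.rm = TRUE)
  cat("<benchmark_result> ", x$plan$n_repeats, " repeats\n", sep = "")
  print(agg, row.names = FALSE)
  if (!is.null(x$comparisons)) {
    cat("pairwise (NB-corrected t, BH):\n")
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}
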