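# Compositional preprocessing: relative-abundance normalization,
# rare-feature filtering (train-set statistics only) and the per-sample
# half-minimum pseudocount.
#
# All three operate on plain samples x features matrices; `preprocess()`
# chains them for `abundance_table`s.

as_values <- function(x) {
  if (inherits(x, "abundance_table")) x$values else as.matrix(x)
}

#' Normalize samples to relative abundances
#'
#' Divides every sample (row) by its total so rows sum to 1.
#'
#' @param x samples x features matrix (or `abundance_table`)
#' @return matrix of the same shape
#' @export
normalize_relative <- function(x) {
  v <- as_values(x)
  tot <- rowSums(v)
  if (any(tot <= 0)) {
    bad <- rownames(v)[tot <= 0]
    stop("sample(s) with zero total abundance: ",
         paste(head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  v / tot
}

#' Filter rare features
#'
#' Keeps exactly the features whose mean abundance and prevalence (fraction
#' of samples with a value > 0) both reach their thresholds; a feature may
#' fail both criteria. The defaults (1e-6 and 1e-2) assume relative
#' abundances. Call this on training samples only and re-use `$kept` on
#' held-out data to avoid leakage.
#'
#' @param x samples x features matrix (or `abundance_table`) of relative
#'   abundances
#' @param mean_abundance_min minimum mean abundance
#' @param prevalence_min minimum prevalence
#' @return list with `table` (filtered matrix), `kept` (feature ids) and
#'   `report` (a `filter_report`: counts of inputs, removals per criterion,
#'   and the thresholds)
#' @export
filter_rare <- function(x, mean_abundance_min = 1e-6, prevalence_min = 1e-2) {
  v <- as_values(x)
  mean_ab <- colMeans(v)
  prev <- colMeans(v > 0)
  fail_ab <- mean_ab < mean_abundance_min
  fail_prev <- prev < prevalence_min
  keep <- !(fail_ab | fail_prev)
  if (!any(keep)) {
    stop("all features removed by the rarity filter; relax ",
         "`mean_abundance_min`/`prevalence_min`", call. = FALSE)
  }
  report <- structure(list(
    n_input = ncol(v),
    n_removed_abundance = sum(fail_ab),
    n_removed_prevalence = sum(fail_prev),
    n_kept = sum(keep),
    thresholds = list(mean_abundance_min = mean_abundance_min,
                      prevalence_min = prevalence_min)
  ), class = "filter_report")
  list(table = v[, keep, drop = FALSE], kept = colnames(v)[keep],
       report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report> kept ", x$n_kept, "/", x$n_input,
      " (", x$n_removed_abundance, " below mean abundance ",
      x$thresholds$mean_abundance_min, ", ", x$n_removed_prevalence,
      " below prevalence ", x$thresholds$prevalence_min, ")\n", sep = "")
  invisible(x)
}

#' Add a per-sample half-minimum pseudocount
#'
#' For each sample, half of its minimum strictly positive value is added to
#' every feature, and the sample is renormalized to sum 1. This removes
#' zeros while preserving the within-sample rank order of features. The
#' minimum is taken over strictly positive values: half of an exact zero
#' would be a no-op and leave the zeros in place.
#'
#' @param x samples x features matrix (or `abundance_table`); every sample
#'   must have at least one strictly positive value
#' @return strictly positive matrix with unit row sums
#' @export
add_pseudocount <- function(x) {
  v <- as_values(x)
  minpos <- apply(v, 1L, function(r) {
    pos <- r[r > 0]
    if (!length(pos)) stop("sample with all-zero abundances", call. = FALSE)
    min(pos)
  })
  out <- v + 0.5 * minpos  # recycles down columns: one constant per sample
  out / rowSums(out)
}

#' Standard preprocessing pipeline
#'
#' Runs, in order: relative-abundance normalization, rare-feature filtering,
#' renormalization, half-minimum pseudocount (itself renormalizing). With
#' `filter_on = "raw"` the filter thresholds are applied to the raw input
#' values before any normalization instead.
#'
#' @param x samples x features matrix or `abundance_table`
#' @param mean_abundance_min,prevalence_min filter thresholds
#' @param filter_on `"relative"` (default) or `"raw"`: the scale on which the
#'   filter statistics are computed
#' @return list with `table` (preprocessed matrix), `kept` (feature ids) and
#'   `report` (the `filter_report`)
#' @export
preprocess <- function(x, mean_abundance_min = 1e-6, prevalence_min = 1e-2,
                       filter_on = c("relative", "raw")) {
  filter_on <- match.arg(filter_on)
  v <- as_values(x)
  fl <- if (filter_on == "raw") {
    filter_rare(v, mean_abundance_min, prevalence_min)
  } else {
    filter_rare(normalize_relative(v), mean_abundance_min, prevalence_min)
  }
  kept <- normalize_relative(fl$table)  # renormalize after dropping columns
  list(table = add_pseudocount(kept), kept = fl$kept, report = fl$report)
}

#' Apply a learned preprocessing to new samples
#'
#' Subsets held-out samples to a previously learned kept-feature list, then
#' renormalizes and pseudocounts. No statistic is computed from the new
#' samples other than their own per-sample totals and minima.
#'
#' @param x samples x features matrix or `abundance_table` (must contain all
#'   kept features)
#' @param kept character vector of feature ids from [filter_rare()]
#' @return preprocessed matrix over `kept`
#' @export
apply_preprocess <- function(x, kept) {
  v <- as_values(x)
  miss <- setdiff(kept, colnames(v))
  if (length(miss)) {
    stop("new table lacks kept feature(s): ",
         paste(head(miss, 10L), collapse = ", "), call. = FALSE)
  }
  add_pseudocount(normalize_relative(v[, kept, drop = FALSE]))
}
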