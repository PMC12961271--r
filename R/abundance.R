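# Abundance tables and file readers.

#' Create an abundance table
#'
#' Light container pairing a samples x features non-negative matrix with the
#' lineage of every feature. Internally the matrix is always samples x
#' features; file readers transpose the common features-as-rows layout.
#'
#' @param values numeric matrix, samples in rows, features in columns; row
#'   and column names are the sample and feature ids
#' @param lineages named list of character vectors (one lineage per feature),
#'   or `NULL` when no taxonomy is attached
#' @return an object of class `abundance_table` with elements `values`,
#'   `lineages`, `sample_ids`, `feature_ids`
#' @export
abundance_table <- function(values, lineages = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be numeric", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` needs sample row names and feature column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate sample ids", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate feature ids", call. = FALSE)
  }
  if (anyNA(values) || any(values < 0)) {
    stop("abundances must be non-negative and non-missing", call. = FALSE)
  }
  if (!is.null(lineages)) {
    miss <- setdiff(colnames(values), names(lineages))
    if (length(miss)) {
      stop("no lineage for feature(s): ", paste(head(miss, 10L), collapse = ", "),
           call. = FALSE)
    }
    lineages <- lineages[colnames(values)]
  }
  structure(list(values = values, lineages = lineages,
                 sample_ids = rownames(values),
                 feature_ids = colnames(values)),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("<abundance_table> ", nrow(x$values), " samples x ", ncol(x$values),
      " features", if (!is.null(x$lineages)) " (with lineages)", "\n", sep = "")
  invisible(x)
}

#' Read an abundance table with lineages from TSV
#'
#' Expects the common microbiome layout: one feature per row, the first
#' column holding the feature id, a `lineage` column with separator-delimited
#' taxon names (optionally rank-prefixed, e.g. `k__Bacteria;p__Firmicutes`),
#' and one column per sample. Use `orientation = "samples-as-rows"` for the
#' transposed layout (there the lineage column is not available). The layout
#' is selected explicitly, never guessed.
#'
#' @param path TSV file path
#' @param orientation `"features-as-rows"` (default) or `"samples-as-rows"`
#' @param lineage_col name of the lineage column
#' @param lineage_sep separator inside the lineage strings (`";"` default,
#'   `"|"` accepted)
#' @return an `abundance_table`
#' @export
read_lineage_tsv <- function(path,
                             orientation = c("features-as-rows",
                                             "samples-as-rows"),
                             lineage_col = "lineage",
                             lineage_sep = ";") {
  orientation <- match.arg(orientation)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (orientation == "samples-as-rows") {
    vals <- as.matrix(df[, -1L, drop = FALSE])
    rownames(vals) <- as.character(df[[1L]])
    return(abundance_table(vals))
  }
  feature_ids <- as.character(df[[1L]])
  if (!lineage_col %in% names(df)) {
    stop("no '", lineage_col, "' column in ", path, call. = FALSE)
  }
  lin_raw <- as.character(df[[lineage_col]])
  lineages <- lapply(strsplit(lin_raw, lineage_sep, fixed = TRUE), trimws)
  names(lineages) <- feature_ids
  sample_cols <- setdiff(names(df)[-1L], lineage_col)
  vals <- t(as.matrix(df[, sample_cols, drop = FALSE]))
  colnames(vals) <- feature_ids
  rownames(vals) <- sample_cols
  abundance_table(vals, lineages)
}

#' Read binary sample labels from a metadata file
#'
#' @param path TSV/CSV file (delimiter inferred from the extension: `.csv`
#'   reads comma-separated, anything else tab-separated)
#' @param label_col name of the label column
#' @param id_col name or index of the sample-id column (default: first)
#' @return named integer vector of 0/1 labels; the attribute `"levels"`
#'   records which original label was coded 1 (the lexicographically larger)
#' @export
read_metadata <- function(path, label_col, id_col = 1L) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!label_col %in% names(df)) {
    stop("no '", label_col, "' column in ", path, call. = FALSE)
  }
  ids <- as.character(df[[id_col]])
  lab <- as.character(df[[label_col]])
  lev <- sort(unique(lab))
  if (length(lev) != 2L) {
    stop("label column must be binary; found levels: ",
         paste(lev, collapse = ", "), call. = FALSE)
  }
  y <- as.integer(lab == lev[2L])
  names(y) <- ids
  attr(y, "levels") <- lev
  y
}

#' Read an abundance table from a BIOM file
#'
#' Thin wrapper around the biomformat package (BIOM v1 JSON and, when HDF5
#' support is available, v2.1). Lineages are taken from the `taxonomy`
#' observation metadata field.
#'
#' @param path BIOM file path
#' @return an `abundance_table`
#' @export
read_biom_table <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop("reading BIOM files requires the 'biomformat' package", call. = FALSE)
  }
  b <- biomformat::read_biom(path)
  vals <- t(as(biomformat::biom_data(b), "matrix"))  # biom is obs x samples
  md <- biomformat::observation_metadata(b)
  lineages <- NULL
  if (!is.null(md)) {
    if (is.data.frame(md)) {
      tax_cols <- grep("taxonomy", names(md), ignore.case = TRUE, value = TRUE)
      if (length(tax_cols)) {
        lineages <- lapply(seq_len(nrow(md)), function(i) {
          toks <- trimws(as.character(unlist(md[i, tax_cols])))
          toks[!is.na(toks) & nzchar(toks)]
        })
        names(lineages) <- rownames(md)
      }
    } else if (is.list(md)) {
      lineages <- lapply(md, function(m) {
        toks <- trimws(as.character(unlist(m)))
        toks[!is.na(toks) & nzchar(toks)]
      })
    }
  }
  abundance_table(vals, lineages)
}
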