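#' Construct an expression dataset
#'
#' Bundles a log2 expression matrix (features in rows, samples in columns)
#' with a binary phenotype and an optional pairing structure. This is the
#' unit of analysis every gene set method in the package consumes.
#'
#' @param expr Numeric matrix of log2 intensities, features x samples.
#' @param group Per-sample phenotype. Accepts 0/1 integers, logicals, or a
#'   two-level factor/character vector; for non-numeric input the first
#'   level in sort order is taken as control (0) and the second as case (1).
#' @param sample_ids Character vector of sample identifiers; defaults to
#'   `colnames(expr)`.
#' @param feature_ids Character vector of probe/gene identifiers; defaults
#'   to `rownames(expr)`.
#' @param block Optional per-sample pairing identifier. When supplied,
#'   every block must contain exactly one case and one control.
#' @param name Dataset label used in benchmark reports.
#'
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `expr`, `feature_ids`, `sample_ids`, `group` (integer 0/1), `block`
#'   (or `NULL`) and `name`.
#' @export
expression_dataset <- function(expr, group, sample_ids = colnames(expr),
                               feature_ids = rownames(expr), block = NULL,
                               name = "dataset") {
  expr <- as.matrix(expr)
  if (!is.numeric(expr)) stop("expression matrix must be numeric")
  if (anyNA(expr)) {
    stop("missing values in expression matrix; reject-by-default (filter or impute upstream)")
  }
  if (is.null(feature_ids)) stop("feature_ids missing and expr has no rownames")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ncol(expr)))
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(expr) != length(feature_ids)) {
    stop("row count does not match number of feature ids")
  }
  if (ncol(expr) != length(sample_ids) || ncol(expr) != length(group)) {
    stop("column count, sample ids and group labels must have equal length")
  }
  if (anyDuplicated(feature_ids)) stop("duplicate feature ids")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  group <- coerce_group(group)
  if (!is.null(block)) {
    block <- as.character(block)
    if (length(block) != length(group)) stop("block must have one entry per sample")
    check_blocks(group, block)
  }
  rownames(expr) <- feature_ids
  colnames(expr) <- sample_ids
  structure(
    list(expr = expr, feature_ids = feature_ids, sample_ids = sample_ids,
         group = group, block = block, name = name),
    class = "ExpressionDataset"
  )
}

coerce_group <- function(group) {
  if (is.numeric(group) || is.logical(group)) {
    g <- as.integer(group)
    if (!all(g %in% c(0L, 1L))) stop("numeric group labels must be 0 (control) or 1 (case)")
  } else {
    lev <- sort(unique(as.character(group)))
    if (length(lev) != 2) stop("group must have exactly two levels")
    g <- as.integer(as.character(group) == lev[2])
  }
  if (sum(g == 0L) < 1 || sum(g == 1L) < 1) stop("both group levels must be present")
  g
}

check_blocks <- function(group, block) {
  tab <- table(block, group)
  if (!all(tab == 1L)) {
    stop("every pairing block must contain exactly one case and one control")
  }
  invisible(TRUE)
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset '%s': %d features x %d samples (%d cases, %d controls)%s\n",
              x$name, nrow(x$expr), ncol(x$expr), sum(x$group == 1L),
              sum(x$group == 0L),
              if (is.null(x$block)) "" else sprintf(", %d paired blocks",
                                                   length(unique(x$block)))))
  invisible(x)
}

#' Is the dataset paired?
#' @param ds An `ExpressionDataset`.
#' @return `TRUE` when a complete pairing structure is present.
#' @export
is_paired <- function(ds) !is.null(ds$block)

#' Construct a gene set collection
#'
#' @param sets Named list of character vectors of gene ids. Set ids must be
#'   unique, each set must be non-empty, and gene ids within a set unique.
#' @param display_names Optional named character vector of human-readable
#'   labels; defaults to the set ids.
#' @return An object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, display_names = NULL) {
  if (length(sets) == 0) stop("empty collection")
  ids <- names(sets)
  if (is.null(ids) || any(ids == "") || anyDuplicated(ids)) {
    stop("sets must be uniquely named")
  }
  sets <- lapply(sets, as.character)
  if (any(lengths(sets) == 0)) stop("every set must be non-empty")
  if (any(vapply(sets, anyDuplicated, 0L) > 0)) {
    stop("gene ids within a set must be unique")
  }
  if (is.null(display_names)) {
    display_names <- stats::setNames(ids, ids)
  } else {
    display_names <- stats::setNames(as.character(display_names[ids]), ids)
    display_names[is.na(display_names)] <- ids[is.na(display_names)]
  }
  structure(list(sets = sets, display_names = display_names),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  sz <- lengths(x$sets)
  cat(sprintf("GeneSetCollection: %d sets, sizes %d-%d (median %g)\n",
              length(x$sets), min(sz), max(sz), stats::median(sz)))
  invisible(x)
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' Set sizes of a collection
#' @param col A `GeneSetCollection`.
#' @return Named integer vector of set sizes.
#' @export
set_sizes <- function(col) lengths(col$sets)

# row indices of each set's genes in a dataset, dropping unmeasured genes
set_index_list <- function(col, feature_ids) {
  lapply(col$sets, function(g) {
    ix <- match(g, feature_ids)
    ix[!is.na(ix)]
  })
}
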