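#' Read a gene set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `set_id<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate gene ids within
#' a line are dropped with a warning; duplicate set ids are an error.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) {
    stop(sprintf("malformed GMT line %d in %s: need >= 3 tab-separated fields",
                 bad[1], path))
  }
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate set id in GMT: ", ids[duplicated(ids)][1])
  }
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  ndup <- vapply(sets, anyDuplicated, 0L)
  if (any(ndup > 0)) {
    warning(sprintf("duplicate gene ids dropped in %d set(s): %s",
                    sum(ndup > 0), paste(ids[ndup > 0], collapse = ", ")))
    sets <- lapply(sets, unique)
  }
  names(sets) <- ids
  gene_set_collection(sets, display_names = stats::setNames(desc, ids))
}

#' Write a gene set collection to a GMT file
#'
#' @param col A `GeneSetCollection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(col, path) {
  lines <- vapply(names(col$sets), function(id) {
    paste(c(id, col$display_names[[id]], col$sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression dataset from TSV files
#'
#' The expression TSV carries feature ids in the first column and one column
#' per sample; the metadata TSV has columns `sample`, `group` and optionally
#' `block`. Expression columns are reordered to the metadata order; a paired
#' design is declared when a complete `block` column is present.
#'
#' @param expr_path Path to the expression TSV.
#' @param meta_path Path to the sample metadata TSV.
#' @param name Dataset label; defaults to the expression file name.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(expr_path, meta_path,
                            name = sub("\\.[^.]*$", "", basename(expr_path))) {
  tab <- utils::read.delim(expr_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  feature_ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric cell in expression matrix: ", expr_path)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(meta))) {
    stop("metadata must have columns 'sample' and 'group'")
  }
  miss <- setdiff(meta$sample, colnames(mat))
  extra <- setdiff(colnames(mat), meta$sample)
  if (length(miss) || length(extra)) {
    stop("sample mismatch between expression and metadata: ",
         paste(c(miss, extra), collapse = ", "))
  }
  mat <- mat[, as.character(meta$sample), drop = FALSE]
  block <- NULL
  if ("block" %in% names(meta) && !anyNA(meta$block)) block <- meta$block
  expression_dataset(mat, group = meta$group, sample_ids = meta$sample,
                     feature_ids = feature_ids, block = block, name = name)
}

#' Write an expression dataset to TSV files
#'
#' Inverse of [read_expression()]: writes the expression matrix (feature ids
#' in the first column) and the sample metadata table.
#'
#' @param ds An `ExpressionDataset`.
#' @param expr_path,meta_path Output paths.
#' @return `expr_path`, invisibly.
#' @export
write_expression <- function(ds, expr_path, meta_path) {
  tab <- data.frame(feature_id = ds$feature_ids, ds$expr,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- data.frame(sample = ds$sample_ids, group = ds$group,
                     stringsAsFactors = FALSE)
  if (!is.null(ds$block)) meta$block <- ds$block
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(expr_path)
}

#' Collapse features to one row per gene
#'
#' Microarray platforms carry multiple probesets per gene; before gene set
#' analysis each gene keeps the probeset with the highest average expression
#' across all samples. Ties are broken by the lexicographically smallest
#' feature id so the choice is reproducible.
#'
#' @param ds An `ExpressionDataset` whose rows are probe-level features.
#' @param feature_to_gene Mapping from feature id to gene id: either a named
#'   character vector (names = feature ids) or a two-column data frame
#'   (feature, gene). Features without a mapping are dropped.
#' @return An `ExpressionDataset` with one row per mapped gene.
#' @export
collapse_features <- function(ds, feature_to_gene) {
  if (is.data.frame(feature_to_gene)) {
    feature_to_gene <- stats::setNames(as.character(feature_to_gene[[2]]),
                                       as.character(feature_to_gene[[1]]))
  }
  if (length(feature_to_gene) == 0) stop("empty feature-to-gene mapping")
  gene <- feature_to_gene[ds$feature_ids]
  keep <- !is.na(gene)
  if (!any(keep)) stop("no feature maps to a gene id")
  expr <- ds$expr[keep, , drop = FALSE]
  gene <- gene[keep]
  feat <- ds$feature_ids[keep]
  avg <- rowMeans(expr)
  # within a gene: descending mean, then lexicographic feature id
  ord <- order(gene, -avg, feat, method = "radix")
  first <- !duplicated(gene[ord])
  tied <- stats::ave(avg, gene, FUN = function(x) sum(x == max(x)))[ord][first]
  if (any(tied > 1)) {
    message(sum(tied > 1), " gene(s) had tied probeset means; kept the smallest feature id")
  }
  pick <- ord[first]
  expression_dataset(expr[pick, , drop = FALSE], group = ds$group,
                     sample_ids = ds$sample_ids, feature_ids = gene[pick],
                     block = ds$block, name = ds$name)
}

#' Restrict a collection to the genes measured in a dataset
#'
#' Every method must see identical set definitions, so sets are intersected
#' with the measured genes up front and sets falling outside the size window
#' are dropped.
#'
#' @param col A `GeneSetCollection`.
#' @param ds An `ExpressionDataset` defining the measured genes.
#' @param min_size,max_size Retained size window after intersection. The
#'   default floor of 3 is the smallest size at which the set statistics are
#'   non-degenerate.
#' @return A restricted `GeneSetCollection`.
#' @export
restrict_collection <- function(col, ds, min_size = 3, max_size = Inf) {
  if (min_size < 1) stop("min_size must be >= 1")
  measured <- ds$feature_ids
  sets <- lapply(col$sets, function(g) g[g %in% measured])
  keep <- lengths(sets) >= min_size & lengths(sets) <= max_size
  if (!any(keep)) stop("no gene set left after restriction")
  gene_set_collection(sets[keep], display_names = col$display_names[keep])
}

#' Write a method result table to TSV
#'
#' @param results Result data frame from [run_method()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
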