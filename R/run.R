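METHOD_IDS <- c("ORA", "MRGSE", "SAFE", "SIGPATHWAY_Q1", "SIGPATHWAY_Q2",
                "GSA", "PADOG", "GAGE", "CAMERA", "GLOBALTEST", "GSEA",
                "GSEAP", "PLAGE", "ZSCORE", "SSGSEA", "GSVA")
GENE_SAMPLING <- c("ORA", "MRGSE", "SIGPATHWAY_Q1", "GAGE", "GSEAP")

#' Registry of gene set analysis methods
#'
#' @return Data frame with columns `method_id` and `sampling_type`
#'   (`"gene"` for competitive methods resampling genes, `"subject"` for
#'   self-contained methods resampling samples).
#' @export
gsa_methods <- function() {
  data.frame(method_id = METHOD_IDS,
             sampling_type = ifelse(METHOD_IDS %in% GENE_SAMPLING,
                                    "gene", "subject"),
             stringsAsFactors = FALSE)
}

match_method <- function(method) {
  m <- toupper(method)
  if (!m %in% METHOD_IDS) {
    stop("unknown method '", method, "'; valid ids: ",
         paste(METHOD_IDS, collapse = ", "))
  }
  m
}

# shared per-run state: restricted collection, set indices, observed gene
# stats and a lazily-built matrix of permutation t-statistics
gsa_context <- function(ds, collection, n_perm = 1000, seed = 1L,
                        min_size = 3) {
  col <- restrict_collection(collection, ds, min_size = min_size)
  e <- new.env(parent = emptyenv())
  e$ds <- ds
  e$col <- col
  e$idx <- set_index_list(col, ds$feature_ids)
  e$n_perm <- n_perm
  e$seed <- as.integer(seed)
  e
}

# gene-level stats are computed on first use: GAGE and the single-sample
# scorers have weaker design requirements than the moderated t
ctx_gs <- function(ctx) {
  if (is.null(ctx$gs)) ctx$gs <- suppressMessages(gene_stats(ctx$ds))
  ctx$gs
}

ctx_tmat <- function(ctx) {
  if (is.null(ctx$tmat)) {
    pp <- permute_samples(ctx$ds, ctx$n_perm, seed = ctx$seed)
    ctx$tmat <- if (pp$paired) {
      d <- paired_differences(ctx$ds$expr, ctx$ds$group, ctx$ds$block)
      perm_t_matrix(ctx$ds$expr, diffs = d, signs = pp$signs)
    } else {
      perm_t_matrix(ctx$ds$expr, labels = pp$labels)
    }
  }
  ctx$tmat
}

finalize_results <- function(ctx, statistic, p_value, method) {
  stopifnot(length(statistic) == length(ctx$idx))
  p_value <- pmin(pmax(p_value, 0), 1)
  out <- data.frame(set_id = names(ctx$idx),
                    size_used = lengths(ctx$idx),
                    statistic = statistic, p_value = p_value,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$rank_pct <- 100 * rank(out$p_value) / nrow(out)
  out <- out[order(out$p_value, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "method_id") <- method
  out
}

#' Run one gene set analysis method on a dataset
#'
#' Restricts the collection to the measured genes, dispatches to the
#' requested statistic and returns one row per analyzed set. Results are
#' deterministic given `seed`.
#'
#' @param ds An `ExpressionDataset`.
#' @param collection A `GeneSetCollection`.
#' @param method A method id from [gsa_methods()].
#' @param n_perm Permutations / random sets for resampling-based nulls.
#' @param seed Integer seed.
#' @param min_size Minimum retained set size after restriction.
#' @param ... Method-specific options (e.g. `tau` for SSGSEA,
#'   `combine` for GAGE, `p_method` for GLOBALTEST).
#' @return Data frame with columns `set_id`, `size_used`, `statistic`,
#'   `p_value` and `rank_pct`, sorted by ascending p-value.
#' @export
run_method <- function(ds, collection, method, n_perm = 1000, seed = 1L,
                       min_size = 3, ...) {
  method <- match_method(method)
  ctx <- gsa_context(ds, collection, n_perm = n_perm, seed = seed,
                     min_size = min_size)
  dispatch_method(ctx, method, ...)
}

dispatch_method <- function(ctx, method, ...) {
  switch(method,
         ORA = m_ora(ctx, ...),
         MRGSE = m_mrgse(ctx),
         SAFE = m_safe(ctx),
         SIGPATHWAY_Q1 = m_sigpathway(ctx, hypothesis = "Q1"),
         SIGPATHWAY_Q2 = m_sigpathway(ctx, hypothesis = "Q2"),
         GSA = m_gsa_maxmean(ctx, ...),
         PADOG = m_padog(ctx),
         GAGE = m_gage(ctx, ...),
         CAMERA = m_camera(ctx),
         GLOBALTEST = m_globaltest(ctx, ...),
         GSEA = m_gsea(ctx),
         GSEAP = m_gseap(ctx),
         PLAGE = m_single_sample(ctx, "PLAGE", ...),
         ZSCORE = m_single_sample(ctx, "ZSCORE", ...),
         SSGSEA = m_single_sample(ctx, "SSGSEA", ...),
         GSVA = m_single_sample(ctx, "GSVA", ...))
}

#' Run several methods on one dataset, sharing the permutation engine
#'
#' All subject-sampling methods reuse a single stream of label permutations
#' and the derived gene-level t-statistics, so a 16-method run costs little
#' more than the most expensive single method. Per-method results are
#' identical to individual [run_method()] calls with the same seed.
#'
#' @inheritParams run_method
#' @param methods Character vector of method ids.
#' @return Named list of result data frames.
#' @export
run_gsa <- function(ds, collection, methods = gsa_methods()$method_id,
                    n_perm = 1000, seed = 1L, min_size = 3, ...) {
  methods <- vapply(methods, match_method, "")
  ctx <- gsa_context(ds, collection, n_perm = n_perm, seed = seed,
                     min_size = min_size)
  out <- lapply(methods, function(m) dispatch_method(ctx, m, ...))
  names(out) <- methods
  out
}

# per-method RNG offsets keep gene-sampling draws independent of which
# other methods share the context
method_seed <- function(ctx, method) {
  (ctx$seed + 131L * match(method, METHOD_IDS)) %% .Machine$integer.max
}

# wrapper used by the exported single-set functions
single_set_result <- function(ds, set, method, n_perm = 1000, seed = 1L,
                              ...) {
  if (is.null(names(set)) && length(set) >= 1 && is.character(set)) {
    col <- gene_set_collection(list(set1 = set))
  } else {
    stop("set must be a character vector of gene ids")
  }
  res <- run_method(ds, col, method, n_perm = n_perm, seed = seed,
                    min_size = 1, ...)
  res[1, , drop = FALSE]
}
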