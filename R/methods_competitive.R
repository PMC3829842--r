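#' Select differentially expressed genes for over-representation analysis
#'
#' Three-stage cascade: (1) all genes at BH-FDR < 0.1 when that list holds
#' more than 200 genes; else (2) all genes with nominal p < 0.05 and fold
#' change above 1.5 (|log2 FC| > log2 1.5) when more than 200; else (3) the
#' top 1 percent of genes by nominal p (`ceiling(G/100)`, ties broken by
#' smaller p then gene id).
#'
#' @param gs A `GeneStats` data frame.
#' @param fdr_cut,p_cut,fc_cut,min_n Cascade thresholds; defaults follow
#'   the standard protocol described above.
#' @return Character vector of DE gene ids.
#' @export
ora_select_de <- function(gs, fdr_cut = 0.1, p_cut = 0.05, fc_cut = 1.5,
                          min_n = 200) {
  r1 <- gs$gene[bh_fdr(gs$p) < fdr_cut]
  if (length(r1) > min_n) return(r1)
  r2 <- gs$gene[gs$p < p_cut & abs(gs$lfc) > log2(fc_cut)]
  if (length(r2) > min_n) return(r2)
  ord <- order(gs$p, gs$gene)
  gs$gene[ord][seq_len(ceiling(nrow(gs) / 100))]
}

#' One-tailed hypergeometric over-representation test
#'
#' `p = P(X >= k)` for `X ~ Hypergeometric(N = |universe|, K = |de|,
#' n = |set|)` with `k` the observed overlap.
#'
#' @param de Character vector of DE gene ids (subset of `universe`).
#' @param universe Character vector of measured gene ids.
#' @param set Character vector of set gene ids (subset of `universe`).
#' @return List with elements `statistic` (the overlap `k`) and `p_value`.
#' @export
ora_test <- function(de, universe, set) {
  if (length(universe) == 0) stop("empty universe")
  de <- intersect(de, universe)
  set <- intersect(set, universe)
  k <- length(intersect(de, set))
  p <- stats::phyper(k - 1, length(de), length(universe) - length(de),
                     length(set), lower.tail = FALSE)
  list(statistic = k, p_value = p)
}

m_ora <- function(ctx, ...) {
  de <- ora_select_de(ctx_gs(ctx), ...)
  universe <- ctx$ds$feature_ids
  res <- lapply(ctx$idx, function(ix) {
    ora_test(de, universe, universe[ix])
  })
  finalize_results(ctx, vapply(res, `[[`, 0, "statistic"),
                   vapply(res, `[[`, 0, "p_value"), "ORA")
}

#' Mean-rank gene set enrichment test (MRGSE)
#'
#' Competitive Wilcoxon rank-sum test comparing the p-value ranks of set
#' genes against all remaining genes, one-sided toward smaller (more
#' significant) ranks. Uses exact enumeration over all equal-size subsets
#' when the universe holds at most 20 genes, otherwise a tie-corrected
#' normal approximation with continuity correction.
#'
#' @param gs A `GeneStats` data frame for the full universe.
#' @param set Character vector of set gene ids.
#' @return List with `statistic` (mean rank of the set genes) and
#'   `p_value`.
#' @export
mean_rank_test <- function(gs, set) {
  ix <- which(gs$gene %in% set)
  mrgse_from_ranks(gs$rank_p, ix)
}

mrgse_from_ranks <- function(r, ix) {
  G <- length(r)
  m <- length(ix)
  if (m < 1) stop("empty set")
  if (m >= G) stop("competitive test needs a non-empty background")
  W <- sum(r[ix])
  if (G <= 20) {
    sums <- colSums(matrix(r[utils::combn(G, m)], nrow = m))
    p <- mean(sums <= W + 1e-9)
  } else {
    mu <- m * (G + 1) / 2
    vpop <- mean(r^2) - mean(r)^2
    vW <- m * (G - m) / (G - 1) * vpop
    p <- stats::pnorm((W + 0.5 - mu) / sqrt(vW))
  }
  list(statistic = W / m, p_value = p)
}

m_mrgse <- function(ctx) {
  r <- ctx_gs(ctx)$rank_p
  res <- lapply(ctx$idx, function(ix) mrgse_from_ranks(r, ix))
  finalize_results(ctx, vapply(res, `[[`, 0, "statistic"),
                   vapply(res, `[[`, 0, "p_value"), "MRGSE")
}
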