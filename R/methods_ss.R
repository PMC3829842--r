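# Single-sample pathway scoring: one activity score per sample per set,
# tested downstream for association with the phenotype by a moderated t.

#' PLAGE metagene scores
#'
#' The set submatrix is row-standardized and decomposed by SVD; the score
#' vector is the projection of the samples on the first principal axis
#' (first right singular vector scaled by its singular value). The sign is
#' fixed so the score correlates non-negatively with the set's mean
#' standardized profile.
#'
#' @param ds An `ExpressionDataset`.
#' @param set Character vector of gene ids.
#' @return Named numeric vector of per-sample scores.
#' @export
plage_scores <- function(ds, set) {
  X <- set_submatrix(ds, set)
  sdv <- sqrt(row_vars(X))
  if (any(sdv == 0)) {
    warning(sum(sdv == 0), " zero-variance gene(s) dropped from PLAGE set")
    X <- X[sdv > 0, , drop = FALSE]
    if (nrow(X) == 0) stop("all set genes have zero variance")
  }
  Z <- standardize_rows(X)
  sv <- svd(Z, nu = 0, nv = 1)
  score <- sv$d[1] * sv$v[, 1]
  if (sum(score * colMeans(Z)) < 0) score <- -score
  stats::setNames(score, ds$sample_ids)
}

#' Z-score pathway activity
#'
#' Per-sample score `sum(z_gs) / sqrt(m)` over the set genes, where `z_gs`
#' is gene g's expression standardized across samples.
#'
#' @inheritParams plage_scores
#' @return Named numeric vector of per-sample scores.
#' @export
zscore_scores <- function(ds, set) {
  X <- set_submatrix(ds, set)
  sdv <- sqrt(row_vars(X))
  if (any(sdv == 0)) {
    warning(sum(sdv == 0), " zero-variance gene(s) dropped from Z-score set")
    X <- X[sdv > 0, , drop = FALSE]
    if (nrow(X) == 0) stop("all set genes have zero variance")
  }
  Z <- standardize_rows(X)
  stats::setNames(colSums(Z) / sqrt(nrow(Z)), ds$sample_ids)
}

#' ssGSEA pathway activity
#'
#' Per sample, genes are ranked by expression (descending) and the score
#' integrates the difference between the rank-weighted in-set ECDF
#' (weights `rank^tau`) and the unweighted out-of-set ECDF. Scores are
#' optionally normalized by their range across samples.
#'
#' @inheritParams plage_scores
#' @param tau Rank-weighting exponent; `tau = 0` gives the plain
#'   integrated ECDF difference.
#' @param normalize Divide the score vector by its max-min range.
#' @return Named numeric vector of per-sample scores.
#' @export
ssgsea_scores <- function(ds, set, tau = 0.25, normalize = TRUE) {
  ix <- set_indices_checked(ds, set)
  if (length(ix) >= nrow(ds$expr)) stop("set must leave a non-empty background")
  s <- ssgsea_engine(ds$expr, list(ix), tau)[1, ]
  if (normalize) {
    rg <- max(s) - min(s)
    if (rg > 0) s <- s / rg
  }
  stats::setNames(s, ds$sample_ids)
}

# closed-form integrated ECDF difference for many sets; rows = sets
ssgsea_engine <- function(expr, idx, tau) {
  G <- nrow(expr)
  n <- ncol(expr)
  out <- matrix(0, length(idx), n)
  tot <- G * (G + 1) / 2
  for (s in seq_len(n)) {
    rk <- rank(expr[, s], ties.method = "average")
    # position in the descending ordering = G - rank + 1 for untied data;
    # use exact positions from the ordering for correctness under ties
    pos <- integer(G)
    pos[order(expr[, s], decreasing = TRUE)] <- seq_len(G)
    decay <- G - pos + 1  # how many positions each gene's step spans
    w <- rk^tau
    for (i in seq_along(idx)) {
      hix <- idx[[i]]
      m <- length(hix)
      W <- sum(w[hix])
      inn <- if (W > 0) sum(w[hix] * decay[hix]) / W else 0
      outn <- (tot - sum(decay[hix])) / (G - m)
      out[i, s] <- inn - outn
    }
  }
  out
}

#' GSVA pathway activity
#'
#' Expression of each gene is mapped through a Gaussian-kernel CDF estimate
#' across samples (bandwidth = per-gene sd / 4) to bring profiles to a
#' common scale; per sample, genes are ranked by the transformed values and
#' a KS-like running statistic (weight 1) is evaluated. The score is the
#' maximum positive deviation plus the minimum negative deviation.
#'
#' @inheritParams plage_scores
#' @return Named numeric vector of per-sample scores.
#' @export
gsva_scores <- function(ds, set) {
  if (ncol(ds$expr) < 3) stop("GSVA needs at least 3 samples")
  ix <- set_indices_checked(ds, set)
  Z <- gsva_transform(ds$expr)
  stats::setNames(gsva_engine(Z, list(ix))[1, ], ds$sample_ids)
}

# Gaussian-kernel CDF transform, genes x samples
gsva_transform <- function(expr, bw_div = 4) {
  n <- ncol(expr)
  sdv <- sqrt(row_vars(expr))
  h <- sdv / bw_div
  Z <- matrix(0.5, nrow(expr), n)
  ok <- h > 0
  if (any(ok)) {
    X <- expr[ok, , drop = FALSE]
    hh <- h[ok]
    for (s in seq_len(n)) {
      acc <- 0
      for (k in seq_len(n)) {
        acc <- acc + stats::pnorm((X[, s] - X[, k]) / hh)
      }
      Z[ok, s] <- acc / n
    }
  }
  Z
}

gsva_engine <- function(Z, idx) {
  n <- ncol(Z)
  out <- matrix(0, length(idx), n)
  for (s in seq_len(n)) {
    zs <- Z[, s]
    ord <- order(zs, decreasing = TRUE)
    sorted <- zs[ord]
    posmap <- integer(length(zs))
    posmap[ord] <- seq_along(zs)
    for (i in seq_along(idx)) {
      hp <- posmap[idx[[i]]]
      ep <- es_parts(sorted, hp, weight_exp = 1)
      out[i, s] <- ep$pos + ep$neg
    }
  }
  out
}

set_submatrix <- function(ds, set) {
  ix <- set_indices_checked(ds, set)
  ds$expr[ix, , drop = FALSE]
}

set_indices_checked <- function(ds, set) {
  ix <- match(set, ds$feature_ids)
  ix <- ix[!is.na(ix)]
  if (length(ix) == 0) stop("no set gene measured in the dataset")
  ix
}

#' Test single-sample pathway scores for phenotype association
#'
#' Applies a paired or unpaired moderated t (matching the dataset's
#' design) across the rows of a set x sample score matrix. With a single
#' set no variance moderation is possible and the ordinary t is used.
#'
#' @param scores Numeric matrix, sets x samples.
#' @param ds The `ExpressionDataset` the scores came from (provides group
#'   and pairing).
#' @return Data frame with columns `set_id`, `statistic` (t) and
#'   `p_value`.
#' @export
ss_association_test <- function(scores, ds) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 1) stop("empty score matrix")
  if (length(unique(ds$group)) < 2) stop("degenerate group")
  prior <- NULL
  if (nrow(scores) == 1) {
    message("single score vector: falling back to the ordinary t-test")
    prior <- list(d0 = 0)
  }
  fit <- suppressMessages(modt_fit(scores, ds$group, ds$block, prior = prior))
  data.frame(set_id = rownames(scores) %||% paste0("set", seq_len(nrow(scores))),
             statistic = fit$t, p_value = fit$p,
             stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

m_single_sample <- function(ctx, method, tau = 0.25, normalize = TRUE, ...) {
  expr <- ctx$ds$expr
  idx <- ctx$idx
  scores <- switch(
    method,
    PLAGE = t(vapply(names(idx), function(id) {
      suppressWarnings(plage_scores(ctx$ds, ctx$col$sets[[id]]))
    }, numeric(ncol(expr)))),
    ZSCORE = t(vapply(names(idx), function(id) {
      suppressWarnings(zscore_scores(ctx$ds, ctx$col$sets[[id]]))
    }, numeric(ncol(expr)))),
    SSGSEA = {
      s <- ssgsea_engine(expr, idx, tau)
      if (normalize) {
        rg <- apply(s, 1, function(x) max(x) - min(x))
        s <- s / ifelse(rg > 0, rg, 1)
      }
      rownames(s) <- names(idx)
      s
    },
    GSVA = {
      if (ncol(expr) < 3) stop("GSVA needs at least 3 samples")
      s <- gsva_engine(gsva_transform(expr), idx)
      rownames(s) <- names(idx)
      s
    })
  rownames(scores) <- names(idx)
  res <- ss_association_test(scores, ctx$ds)
  finalize_results(ctx, res$statistic, res$p_value, method)
}
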