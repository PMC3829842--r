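#' Gene-level moderated t-statistics
#'
#' Computes per-gene differential expression between cases and controls with
#' empirical-Bayes variance moderation: ordinary residual variances s^2 with
#' d residual degrees of freedom are shrunk toward a prior s0^2 with d0 prior
#' degrees of freedom, s2_post = (d0*s0^2 + d*s^2)/(d0 + d), and
#' t = effect / sqrt(s2_post * c) is referred to a t distribution on d0 + d
#' degrees of freedom. The hyperparameters (s0^2, d0) are estimated by
#' moment-matching the scaled-F marginal of the sample variances
#' (via [limma::squeezeVar()]). Paired designs are analyzed as a one-sample
#' moderated t on within-block case-minus-control differences.
#'
#' @param ds An `ExpressionDataset`. Unpaired designs need at least two
#'   samples per group; paired designs at least two blocks.
#' @param prior Optional list `list(d0=, s02=)` overriding the estimated
#'   hyperparameters; `d0 = 0` recovers the ordinary per-gene t and
#'   `d0 = Inf` the pooled-variance t with common variance `s02`. Used for
#'   shrinkage-limit analyses; leave `NULL` for the estimated prior.
#' @return A data frame of class `GeneStats` with columns `gene`, `lfc`
#'   (log2 fold change, case minus control), `t`, `p`, `s2_post` and
#'   `rank_p` (1..G ranking by p, average ties), plus attributes `d0`,
#'   `s02`, `df_resid` and `paired`.
#' @export
gene_stats <- function(ds, prior = NULL) {
  fit <- modt_fit(ds$expr, ds$group, ds$block, prior = prior)
  out <- data.frame(gene = ds$feature_ids, lfc = fit$effect, t = fit$t,
                    p = fit$p, s2_post = fit$s2_post,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$rank_p <- rank(out$p)
  attr(out, "d0") <- fit$d0
  attr(out, "s02") <- fit$s02
  attr(out, "df_resid") <- fit$df
  attr(out, "paired") <- fit$paired
  class(out) <- c("GeneStats", "data.frame")
  out
}

#' @rdname gene_stats
#' @export
moderated_t <- gene_stats

row_vars <- function(x, means = rowMeans(x)) {
  n <- ncol(x)
  pmax((rowSums(x * x) - n * means * means) / (n - 1), 0)
}

# per-gene effect, pooled variance, residual df and design constant
modt_summaries <- function(expr, group, block = NULL) {
  if (!is.null(block)) {
    d <- paired_differences(expr, group, block)
    nb <- ncol(d)
    if (nb < 2) stop("paired design needs at least two complete blocks")
    effect <- rowMeans(d)
    list(effect = effect, s2 = row_vars(d, effect), df = nb - 1,
         c_const = 1 / nb, paired = TRUE)
  } else {
    i1 <- group == 1L
    n1 <- sum(i1); n0 <- sum(!i1)
    if (n1 < 2 || n0 < 2) stop("unpaired design needs at least two samples per group")
    m1 <- rowMeans(expr[, i1, drop = FALSE])
    m0 <- rowMeans(expr[, !i1, drop = FALSE])
    v1 <- row_vars(expr[, i1, drop = FALSE], m1)
    v0 <- row_vars(expr[, !i1, drop = FALSE], m0)
    s2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    list(effect = m1 - m0, s2 = s2, df = n1 + n0 - 2,
         c_const = 1 / n1 + 1 / n0, paired = FALSE)
  }
}

# case-minus-control difference matrix, one column per block
paired_differences <- function(expr, group, block) {
  blocks <- unique(block)
  ic <- vapply(blocks, function(b) which(block == b & group == 1L)[1], 0L)
  i0 <- vapply(blocks, function(b) which(block == b & group == 0L)[1], 0L)
  d <- expr[, ic, drop = FALSE] - expr[, i0, drop = FALSE]
  colnames(d) <- blocks
  d
}

modt_fit <- function(expr, group, block = NULL, prior = NULL) {
  sm <- modt_summaries(expr, group, block)
  sh <- shrink_vars(sm$s2, sm$df, prior)
  tt <- sm$effect / sqrt(sh$s2_post * sm$c_const)
  # total df capped at the pooled residual df across genes, so an infinite
  # prior still yields a t (not normal) reference distribution
  dft <- min(sm$df + sh$d0, length(sm$s2) * sm$df)
  p <- 2 * stats::pt(abs(tt), df = dft, lower.tail = FALSE)
  degen <- !is.finite(tt)
  if (any(degen)) {
    # all-constant genes: zero effect and zero posterior variance
    message(sum(degen), " gene(s) with zero posterior variance set to t = 0, p = 1")
    tt[degen] <- 0
    p[degen] <- 1
  }
  p <- pmax(p, .Machine$double.xmin)
  list(effect = sm$effect, t = tt, p = p, s2_post = sh$s2_post,
       d0 = sh$d0, s02 = sh$s02, df = sm$df, paired = sm$paired)
}

shrink_vars <- function(s2, df, prior = NULL) {
  if (is.null(prior)) {
    if (all(s2 <= 0)) {
      # fully degenerate data; no shrinkage possible
      return(list(s2_post = s2, d0 = 0, s02 = NA_real_))
    }
    sv <- limma::squeezeVar(s2, df = df)
    s02 <- if (is.null(sv$var.prior)) NA_real_ else sv$var.prior
    return(list(s2_post = sv$var.post, d0 = sv$df.prior, s02 = s02))
  }
  d0 <- prior$d0
  if (is.infinite(d0)) {
    s02 <- if (is.null(prior$s02)) mean(s2) else prior$s02
    return(list(s2_post = rep(s02, length(s2)), d0 = Inf, s02 = s02))
  }
  if (d0 == 0) return(list(s2_post = s2, d0 = 0, s02 = NA_real_))
  s02 <- prior$s02
  list(s2_post = (d0 * s02 + df * s2) / (d0 + df), d0 = d0, s02 = s02)
}

# fast t-statistics for a batch of permuted labelings; columns of `labels`
# are 0/1 group vectors (unpaired) or +/-1 block sign vectors (paired, with
# `diffs` the block difference matrix)
perm_t_matrix <- function(expr, labels = NULL, diffs = NULL, signs = NULL) {
  if (is.null(signs)) {
    n1 <- sum(labels[, 1]); n0 <- nrow(labels) - n1
    s1 <- expr %*% labels
    s0 <- rowSums(expr) - s1
    q1 <- (expr * expr) %*% labels
    q0 <- rowSums(expr * expr) - q1
    m1 <- s1 / n1; m0 <- s0 / n0
    v1 <- pmax(q1 - n1 * m1 * m1, 0) / (n1 - 1)
    v0 <- pmax(q0 - n0 * m0 * m0, 0) / (n0 - 1)
    s2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    eff <- m1 - m0
    df <- n1 + n0 - 2
    cc <- 1 / n1 + 1 / n0
  } else {
    nb <- nrow(signs)
    eff <- (diffs %*% signs) / nb
    q <- rowSums(diffs * diffs)
    s2 <- pmax(q - nb * eff * eff, 0) / (nb - 1)
    df <- nb - 1
    cc <- 1 / nb
  }
  tmat <- matrix(0, nrow(eff), ncol(eff))
  for (b in seq_len(ncol(eff))) {
    sh <- shrink_vars(s2[, b], df)
    tb <- eff[, b] / sqrt(sh$s2_post * cc)
    tb[!is.finite(tb)] <- 0
    tmat[, b] <- tb
  }
  tmat
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Monotone step-up adjustment of a vector of p-values.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of adjusted p-values.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Rank genes by a differential-expression key
#'
#' @param gs A `GeneStats` data frame from [gene_stats()].
#' @param key One of `"p"` (ascending), `"t"`, `"abs_t"` or `"lfc"`
#'   (descending). Ties receive the average rank.
#' @return Numeric vector of ranks, one per gene.
#' @export
rank_genes <- function(gs, key = c("p", "t", "abs_t", "lfc")) {
  key <- match.arg(key)
  x <- switch(key, p = gs$p, t = -gs$t, abs_t = -abs(gs$t), lfc = -gs$lfc)
  rank(x)
}
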