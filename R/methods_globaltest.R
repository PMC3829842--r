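# GLOBALTEST: score test for association between a set's expression and a
# binary phenotype. Q = (y - ybar)' X'X (y - ybar) / m with X the
# row-standardized set submatrix; large Q means samples with similar set
# profiles share a phenotype. The default p-value moment-matches a scaled
# chi-square to the permutation null of the quadratic form; an explicit
# permutation p is available as a fallback.

globaltest_q <- function(X, y) {
  a <- y - mean(y)
  A <- crossprod(X)  # samples x samples inner products
  list(q = drop(a %*% A %*% a) / nrow(X), A = A, a = a)
}

standardize_rows <- function(X) {
  mu <- rowMeans(X)
  sdv <- sqrt(row_vars(X, mu))
  Z <- (X - mu) / ifelse(sdv > 0, sdv, 1)
  Z[sdv == 0, ] <- 0  # constant genes carry no information
  Z
}

# Exact permutation mean and variance of T = sum over a random k-subset S
# of the submatrix A[S, S], for symmetric A with zero row sums (the kernel
# of row-standardized expression is doubly centered). Because A1 = 0, the
# score statistic (y - ybar)' A (y - ybar) equals T for the case subset,
# so these are the exact first two permutation moments of the statistic.
subset_quadratic_moments <- function(A, k) {
  n <- nrow(A)
  d <- diag(A)
  sd1 <- sum(d)
  sd2 <- sum(d^2)
  po <- sum(A^2) - sd2  # off-diagonal squared mass
  p1 <- k / n
  p2 <- k * (k - 1) / (n * (n - 1))
  p3 <- p2 * (k - 2) / (n - 2)
  p4 <- p3 * (k - 3) / (n - 3)
  ET <- sd1 * k * (n - k) / (n * (n - 1))
  ET2 <- p1 * sd2 + p2 * (sd1^2 - sd2) +
    2 * (-2 * p2 * sd2 + p3 * (2 * sd2 - sd1^2)) +
    2 * p2 * po + 4 * p3 * (sd2 - po) +
    p4 * (sd1^2 + 2 * po - 4 * sd2)
  list(mean = ET, var = max(ET2 - ET^2, 0))
}

globaltest_single <- function(X, y, p_method = "chisq", n_perm = 1000) {
  n <- ncol(X)
  Z <- standardize_rows(X)
  gt <- globaltest_q(Z, y)
  A <- gt$A
  a <- gt$a
  if (sum(diag(A)) <= .Machine$double.eps) {
    return(list(statistic = 0, p_value = 1))
  }
  if (p_method == "chisq") {
    # Satterthwaite scaled chi-square matched to the exact permutation
    # moments of the quadratic form under the binary phenotype
    mo <- subset_quadratic_moments(A, sum(y == 1L))
    if (mo$var <= 0) return(list(statistic = gt$q, p_value = 1))
    q_raw <- gt$q * nrow(Z)  # un-divide by m; moments are for a'Aa
    scale <- mo$var / (2 * mo$mean)
    nu <- 2 * mo$mean^2 / mo$var
    p <- stats::pchisq(q_raw / scale, df = nu, lower.tail = FALSE)
  } else {
    P <- vapply(seq_len(n_perm), function(i) sample(a), numeric(n))
    qn <- colSums(P * (A %*% P)) / nrow(Z)
    p <- permutation_pvalue(gt$q, qn, "greater")
  }
  list(statistic = gt$q, p_value = p)
}

m_globaltest <- function(ctx, p_method = c("chisq", "permutation")) {
  p_method <- match.arg(p_method)
  y <- ctx$ds$group
  if (length(unique(y)) < 2) stop("constant phenotype")
  set.seed(method_seed(ctx, "GLOBALTEST"))
  res <- lapply(ctx$idx, function(ix) {
    globaltest_single(ctx$ds$expr[ix, , drop = FALSE], y,
                      p_method = p_method, n_perm = ctx$n_perm)
  })
  finalize_results(ctx, vapply(res, `[[`, 0, "statistic"),
                   vapply(res, `[[`, 0, "p_value"), "GLOBALTEST")
}

#' Global test for a single set
#'
#' Score statistic `Q = (y - ybar)' R (y - ybar) / m` with `R` the
#' inner-product matrix of the row-standardized set expression.
#' Significance from a Satterthwaite scaled chi-square moment-matched to
#' the exchangeable-phenotype null (default), or by explicit label
#' permutation.
#'
#' @inheritParams safe_test
#' @param p_method `"chisq"` (moment matching) or `"permutation"`.
#' @return One-row result data frame.
#' @export
globaltest_test <- function(ds, set, p_method = "chisq", n_perm = 1000,
                            seed = 1L) {
  single_set_result(ds, set, "GLOBALTEST", n_perm, seed,
                    p_method = p_method)
}
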