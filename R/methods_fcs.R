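# Functional class scoring statistics with resampling nulls. All
# sample-permutation methods consume the shared t-statistic matrix from
# ctx_tmat() so the 1000-permutation contract is enforced uniformly.

# ---- SAFE: Wilcoxon rank sum of |t| ranks, sample-permutation null ----

safe_stat <- function(tvec, idx) {
  rk <- rank(abs(tvec))
  vapply(idx, function(ix) sum(rk[ix]), 0)
}

m_safe <- function(ctx) {
  if (any(lengths(ctx$idx) >= nrow(ctx$ds$expr))) {
    stop("competitive statistic needs a non-empty background")
  }
  obs <- safe_stat(ctx_gs(ctx)$t, ctx$idx)
  tmat <- ctx_tmat(ctx)
  nulls <- apply(tmat, 2, safe_stat, idx = ctx$idx)
  nulls <- matrix(nulls, nrow = length(ctx$idx))
  p <- vapply(seq_along(obs), function(i) {
    permutation_pvalue(obs[i], nulls[i, ], "greater")
  }, 0)
  finalize_results(ctx, obs, p, "SAFE")
}

#' SAFE gene set test for a single set
#'
#' Local statistic: moderated t per gene; global statistic: Wilcoxon rank
#' sum of the |t| ranks of set genes; significance by sample permutation.
#'
#' @param ds An `ExpressionDataset`.
#' @param set Character vector of gene ids.
#' @param n_perm,seed Permutation settings.
#' @return One-row result data frame.
#' @export
safe_test <- function(ds, set, n_perm = 1000, seed = 1L) {
  single_set_result(ds, set, "SAFE", n_perm, seed)
}

# ---- SIGPATHWAY Q1/Q2: standardized mean of gene scores ----

sig_standardize <- function(obs, nulls) {
  mu <- mean(nulls)
  sdv <- stats::sd(nulls)
  if (!is.finite(sdv) || sdv == 0) {
    return(list(z = 0, p = 1))
  }
  z <- (obs - mu) / sdv
  znull <- (nulls - mu) / sdv
  list(z = z, p = permutation_pvalue(z, znull, "two"))
}

m_sigpathway <- function(ctx, hypothesis = c("Q1", "Q2")) {
  hypothesis <- match.arg(hypothesis)
  tv <- ctx_gs(ctx)$t
  obs <- vapply(ctx$idx, function(ix) mean(tv[ix]), 0)
  G <- length(tv)
  if (hypothesis == "Q1") {
    set.seed(method_seed(ctx, "SIGPATHWAY_Q1"))
    sizes <- lengths(ctx$idx)
    nulls_by_size <- lapply(unique(sizes), function(m) {
      idxm <- random_set_indices(G, m, ctx$n_perm)
      colMeans(matrix(tv[idxm], nrow = m))
    })
    names(nulls_by_size) <- as.character(unique(sizes))
    res <- lapply(seq_along(obs), function(i) {
      sig_standardize(obs[i], nulls_by_size[[as.character(sizes[i])]])
    })
  } else {
    tmat <- ctx_tmat(ctx)
    res <- lapply(seq_along(obs), function(i) {
      ix <- ctx$idx[[i]]
      sig_standardize(obs[i], colSums(tmat[ix, , drop = FALSE]) / length(ix))
    })
  }
  finalize_results(ctx, vapply(res, `[[`, 0, "z"),
                   vapply(res, `[[`, 0, "p"), paste0("SIGPATHWAY_", hypothesis))
}

#' SIGPATHWAY gene set test for a single set
#'
#' Set statistic: standardized mean of the moderated t-scores of set genes.
#' Hypothesis Q1 draws its null from random equal-size gene sets; Q2 from
#' sample-label permutations.
#'
#' @inheritParams safe_test
#' @param hypothesis `"Q1"` (gene sampling) or `"Q2"` (sample permutation).
#' @return One-row result data frame.
#' @export
sigpathway_test <- function(ds, set, hypothesis = c("Q1", "Q2"),
                            n_perm = 1000, seed = 1L) {
  hypothesis <- match.arg(hypothesis)
  single_set_result(ds, set, paste0("SIGPATHWAY_", hypothesis), n_perm, seed)
}

# ---- GSA: restandardized maxmean, sample-permutation null ----

#' The maxmean set statistic
#'
#' `s+` is the mean of the positive parts of the gene scores, `s-` the mean
#' of the negative parts; maxmean is whichever is larger in magnitude, with
#' the sign of the dominating direction retained.
#'
#' @param tvals Numeric vector of gene-level scores for the set genes.
#' @return Signed maxmean statistic.
#' @export
maxmean_stat <- function(tvals) {
  sp <- sum(pmax(tvals, 0)) / length(tvals)
  sn <- sum(pmax(-tvals, 0)) / length(tvals)
  if (sp >= sn) sp else -sn
}

# maxmean for R random sets (columns of an index matrix) on each column of
# a t matrix; returns R x B
maxmean_ensemble <- function(tmat, idxmat) {
  m <- nrow(idxmat); R <- ncol(idxmat)
  grp <- rep(seq_len(R), each = m)
  tv <- tmat[as.vector(idxmat), , drop = FALSE]
  sp <- rowsum(pmax(tv, 0), grp) / m
  sn <- rowsum(pmax(-tv, 0), grp) / m
  ifelse(sp >= sn, sp, -sn)
}

m_gsa_maxmean <- function(ctx, n_restand = 100) {
  sizes <- lengths(ctx$idx)
  if (any(sizes < 2)) stop("maxmean needs sets of size >= 2")
  tv <- ctx_gs(ctx)$t
  tmat <- ctx_tmat(ctx)
  G <- length(tv)
  set.seed(method_seed(ctx, "GSA"))
  usz <- unique(sizes)
  ens_idx <- lapply(usz, function(m) random_set_indices(G, m, n_restand))
  names(ens_idx) <- as.character(usz)
  both <- cbind(tv, tmat)  # column 1 = observed, rest = permutations
  stat <- p <- numeric(length(sizes))
  for (m in usz) {
    ens <- maxmean_ensemble(both, ens_idx[[as.character(m)]])
    mu <- colMeans(ens)
    sdv <- apply(ens, 2, stats::sd)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    for (i in which(sizes == m)) {
      ix <- ctx$idx[[i]]
      mm <- maxmean_ensemble(both, matrix(ix, ncol = 1))  # 1 x (B+1)
      std <- (as.vector(mm) - mu) / sdv
      stat[i] <- std[1]
      p[i] <- permutation_pvalue(std[1], std[-1], "two")
    }
  }
  finalize_results(ctx, stat, p, "GSA")
}

#' GSA maxmean test for a single set
#'
#' Maxmean statistic restandardized by the mean and standard deviation of
#' maxmean over random gene sets of equal size; significance by two-sided
#' sample permutation of the restandardized statistic.
#'
#' @inheritParams safe_test
#' @param n_restand Number of random sets in the restandardization
#'   ensemble.
#' @return One-row result data frame.
#' @export
gsa_maxmean_test <- function(ds, set, n_perm = 1000, seed = 1L,
                             n_restand = 100) {
  single_set_result(ds, set, "GSA", n_perm, seed, n_restand = n_restand)
}

# ---- PADOG: frequency-downweighted mean |t| ----

#' PADOG gene weights from set-membership frequencies
#'
#' Gene frequency `f` is the number of analyzed sets containing the gene;
#' the weight is `1 + sqrt((f_max - f) / (f_max - f_min))` so ubiquitous
#' genes are down-weighted. All weights are 1 when every gene has the same
#' frequency.
#'
#' @param col A `GeneSetCollection` (already restricted to measured genes).
#' @return Named numeric vector of weights over all genes in the
#'   collection.
#' @export
padog_weights <- function(col) {
  f <- table(unlist(col$sets, use.names = FALSE))
  fmax <- max(f); fmin <- min(f)
  w <- if (fmax == fmin) rep(1, length(f)) else 1 + sqrt((fmax - as.numeric(f)) / (fmax - fmin))
  stats::setNames(as.numeric(w), names(f))
}

padog_scores <- function(abs_t_w, idx) {
  vapply(idx, function(ix) mean(abs_t_w[ix]), 0)
}

std_within <- function(x) {
  sdv <- stats::sd(x)
  if (!is.finite(sdv) || sdv == 0) return(rep(0, length(x)))
  (x - mean(x)) / sdv
}

m_padog <- function(ctx) {
  w <- rep(1, nrow(ctx$ds$expr))
  wk <- padog_weights(ctx$col)
  hit <- match(names(wk), ctx$ds$feature_ids)
  w[hit[!is.na(hit)]] <- wk[!is.na(hit)]
  obs <- std_within(padog_scores(abs(ctx_gs(ctx)$t) * w, ctx$idx))
  tmat <- ctx_tmat(ctx)
  nulls <- apply(abs(tmat) * w, 2, padog_scores, idx = ctx$idx)
  nulls <- matrix(nulls, nrow = length(ctx$idx))
  nulls <- apply(nulls, 2, std_within)
  nulls <- matrix(nulls, nrow = length(ctx$idx))
  p <- vapply(seq_along(obs), function(i) {
    permutation_pvalue(obs[i], nulls[i, ], "greater")
  }, 0)
  finalize_results(ctx, obs, p, "PADOG")
}

#' PADOG test for a single set within a collection
#'
#' The collection matters: gene weights derive from membership frequencies
#' across all analyzed sets.
#'
#' @param ds An `ExpressionDataset`.
#' @param collection The full `GeneSetCollection` being analyzed.
#' @param set_id Id of the set of interest.
#' @param n_perm,seed,min_size Run settings.
#' @return One-row result data frame.
#' @export
padog_test <- function(ds, collection, set_id, n_perm = 1000, seed = 1L,
                       min_size = 3) {
  if (!set_id %in% names(collection$sets)) {
    stop("set '", set_id, "' not in collection")
  }
  res <- run_method(ds, collection, "PADOG", n_perm = n_perm, seed = seed,
                    min_size = min_size)
  res[res$set_id == set_id, , drop = FALSE]
}

# ---- GAGE: mean fold change of set vs background, 1-on-group ----

m_gage <- function(ctx, combine = c("stouffer", "fisher")) {
  combine <- match.arg(combine)
  expr <- ctx$ds$expr
  ctrl <- rowMeans(expr[, ctx$ds$group == 0L, drop = FALSE])
  cases <- which(ctx$ds$group == 1L)
  G <- nrow(expr)
  zmat <- matrix(0, length(ctx$idx), length(cases))
  for (j in seq_along(cases)) {
    fc <- expr[, cases[j]] - ctrl
    s_all <- sum(fc); q_all <- sum(fc * fc)
    for (i in seq_along(ctx$idx)) {
      ix <- ctx$idx[[i]]
      m <- length(ix)
      s_in <- sum(fc[ix]); q_in <- sum(fc[ix]^2)
      n_out <- G - m
      m_in <- s_in / m; m_out <- (s_all - s_in) / n_out
      v_in <- max(q_in - m * m_in^2, 0) / max(m - 1, 1)
      v_out <- max((q_all - q_in) - n_out * m_out^2, 0) / max(n_out - 1, 1)
      se <- sqrt(v_in / m + v_out / n_out)
      if (se == 0) { zmat[i, j] <- 0; next }
      tt <- (m_in - m_out) / se
      df <- (v_in / m + v_out / n_out)^2 /
        (ifelse(v_in > 0, (v_in / m)^2 / (m - 1), 0) +
           ifelse(v_out > 0, (v_out / n_out)^2 / (n_out - 1), 0))
      p1 <- stats::pt(tt, df)  # lower-tail one-sided p
      p1 <- min(max(p1, 1e-300), 1 - 1e-16)
      zmat[i, j] <- stats::qnorm(p1)
    }
  }
  k <- length(cases)
  if (combine == "stouffer") {
    z <- rowSums(zmat) / sqrt(k)
    p <- 2 * stats::pnorm(-abs(z))
  } else {
    # Fisher on two-sided per-comparison p-values; direction not retained
    p2 <- 2 * stats::pnorm(-abs(zmat))
    chi <- -2 * rowSums(log(pmax(p2, 1e-300)))
    p <- stats::pchisq(chi, df = 2 * k, lower.tail = FALSE)
    z <- chi
  }
  finalize_results(ctx, z, p, "GAGE")
}

#' GAGE test for a single set
#'
#' For each case sample, per-gene fold changes against the control-group
#' mean are compared between set and background via a two-sample t-test;
#' the per-comparison p-values are combined assuming independence
#' (Stouffer on signed z by default, Fisher optionally).
#'
#' @inheritParams safe_test
#' @param combine `"stouffer"` (default, preserves direction) or
#'   `"fisher"`.
#' @return One-row result data frame.
#' @export
gage_test <- function(ds, set, combine = "stouffer", seed = 1L) {
  single_set_result(ds, set, "GAGE", n_perm = 1, seed = seed,
                    combine = combine)
}

# ---- CAMERA: correlation-adjusted competitive test ----

camera_vif <- function(resid_set) {
  m <- nrow(resid_set)
  v <- row_vars(resid_set)
  keep <- v > 0
  if (sum(keep) < 2) return(list(rho = 0, vif = 1))
  cc <- stats::cor(t(resid_set[keep, , drop = FALSE]))
  rho <- mean(cc[upper.tri(cc)])
  vif <- max(1 + (m - 1) * rho, .Machine$double.eps)
  list(rho = rho, vif = vif)
}

m_camera <- function(ctx) {
  tv <- ctx_gs(ctx)$t
  G <- length(tv)
  sd_all <- stats::sd(tv)
  expr <- ctx$ds$expr
  g1 <- ctx$ds$group == 1L
  resid <- expr
  resid[, g1] <- expr[, g1, drop = FALSE] - rowMeans(expr[, g1, drop = FALSE])
  resid[, !g1] <- expr[, !g1, drop = FALSE] - rowMeans(expr[, !g1, drop = FALSE])
  res <- lapply(ctx$idx, function(ix) {
    m <- length(ix)
    if (m < 2) stop("CAMERA needs sets of size >= 2")
    vf <- camera_vif(resid[ix, , drop = FALSE])
    delta <- mean(tv[ix]) - mean(tv[-ix])
    se <- sd_all * sqrt(vf$vif / m + 1 / (G - m))
    z <- if (se == 0) 0 else delta / se
    list(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  finalize_results(ctx, vapply(res, `[[`, 0, "z"),
                   vapply(res, `[[`, 0, "p"), "CAMERA")
}

#' CAMERA test for a single set
#'
#' Standardized mean difference of moderated t-scores between set and
#' background, with the variance inflated by `1 + (m - 1) * rho` where
#' `rho` is the mean inter-gene correlation estimated from the set genes'
#' residuals (group means removed); two-sided normal p-value.
#'
#' @inheritParams safe_test
#' @return One-row result data frame.
#' @export
camera_test <- function(ds, set, seed = 1L) {
  single_set_result(ds, set, "CAMERA", n_perm = 1, seed = seed)
}
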