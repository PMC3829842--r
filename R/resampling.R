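#' Sample-label permutations for a dataset
#'
#' Generates group-label relabelings preserving group sizes. Paired designs
#' are permuted by independent case/control swaps within each block. When
#' the number of distinct non-identity permutations is at most `n_perm` the
#' full set is enumerated (identity excluded) instead of sampled, removing
#' Monte-Carlo noise on tiny designs.
#'
#' @param ds An `ExpressionDataset`.
#' @param n_perm Number of permutations requested.
#' @param seed Integer seed; the stream is reproducible given the seed.
#' @return A list of class `sample_permutations` with elements `labels`
#'   (samples x draws matrix of 0/1 labels), `signs` (blocks x draws matrix
#'   of +/-1 swaps for paired designs, else `NULL`), `paired` and
#'   `exhaustive`.
#' @export
permute_samples <- function(ds, n_perm = 1000, seed = 1L) {
  group <- ds$group
  n <- length(group)
  set.seed(seed)
  if (is_paired(ds)) {
    blocks <- unique(ds$block)
    nb <- length(blocks)
    total <- 2^nb
    if (total - 1 <= n_perm) {
      signs <- as.matrix(expand.grid(rep(list(c(1, -1)), nb)))[-1, , drop = FALSE]
      signs <- t(signs)  # blocks x draws; first row dropped was identity
      exhaustive <- TRUE
    } else {
      signs <- matrix(sample(c(1, -1), nb * n_perm, replace = TRUE), nb, n_perm)
      exhaustive <- FALSE
    }
    rownames(signs) <- blocks
    labels <- matrix(group, n, ncol(signs))
    for (k in seq_len(nb)) {
      flip <- signs[k, ] == -1
      rows <- which(ds$block == blocks[k])
      labels[rows, flip] <- 1L - group[rows]
    }
    out <- list(labels = labels, signs = signs, paired = TRUE,
                exhaustive = exhaustive)
  } else {
    n1 <- sum(group == 1L)
    if (n1 < 2 || n - n1 < 2) stop("degenerate design: need two samples per group")
    total <- choose(n, n1)
    if (total - 1 <= n_perm) {
      cols <- utils::combn(n, n1)
      labels <- matrix(0L, n, ncol(cols))
      labels[cbind(as.vector(cols), rep(seq_len(ncol(cols)), each = n1))] <- 1L
      labels <- labels[, colSums(labels == group) < n, drop = FALSE]
      exhaustive <- TRUE
    } else {
      labels <- vapply(seq_len(n_perm), function(i) sample(group), integer(n))
      exhaustive <- FALSE
    }
    out <- list(labels = labels, signs = NULL, paired = FALSE,
                exhaustive = exhaustive)
  }
  class(out) <- "sample_permutations"
  out
}

#' Random gene sets of fixed size
#'
#' Uniform without-replacement sets of size `m` from a universe of gene ids,
#' the null generator of gene-sampling methods. When `choose(|universe|, m)`
#' is at most `n_perm`, all subsets are enumerated exactly once.
#'
#' @param universe Character vector of gene ids.
#' @param m Set size.
#' @param n_perm Number of sets requested.
#' @param seed Integer seed.
#' @return List of character vectors, with attribute `exhaustive`.
#' @export
sample_random_sets <- function(universe, m, n_perm = 1000, seed = 1L) {
  idx <- random_set_indices(length(universe), m, n_perm, seed)
  out <- lapply(seq_len(ncol(idx)), function(j) universe[idx[, j]])
  attr(out, "exhaustive") <- attr(idx, "exhaustive")
  out
}

# m x draws index matrix; exhaustive when the subset space fits in n_perm
random_set_indices <- function(n, m, n_perm, seed = NULL) {
  if (m > n) stop("set size exceeds universe size")
  if (!is.null(seed)) set.seed(seed)
  if (choose(n, m) <= n_perm) {
    idx <- utils::combn(n, m)
    attr(idx, "exhaustive") <- TRUE
  } else {
    idx <- vapply(seq_len(n_perm), function(i) sample.int(n, m), integer(m))
    idx <- matrix(idx, nrow = m)
    attr(idx, "exhaustive") <- FALSE
  }
  idx
}

#' Permutation p-value
#'
#' `p = (b + 1) / (B + 1)` where `b` counts null statistics at least as
#' extreme as the observed one; the +1 guards against zero p-values. The
#' two-sided variant compares absolute values and is meant for statistics
#' whose null is centered at zero.
#'
#' @param observed Observed statistic (finite scalar).
#' @param nulls Vector of null statistics.
#' @param sided `"greater"`, `"less"` or `"two"`.
#' @return A p-value in `[1/(B+1), 1]`.
#' @export
permutation_pvalue <- function(observed, nulls,
                               sided = c("greater", "less", "two")) {
  sided <- match.arg(sided)
  if (!is.finite(observed)) stop("observed statistic must be finite")
  if (length(nulls) < 1) stop("need at least one null statistic")
  b <- switch(sided,
              greater = sum(nulls >= observed),
              less = sum(nulls <= observed),
              two = sum(abs(nulls) >= abs(observed)))
  (b + 1) / (length(nulls) + 1)
}

#' Phenotype-permutation specificity experiment
#'
#' Estimates per-method false-positive rates in the absence of real
#' differential expression but with gene-gene correlations intact: each
#' dataset's phenotype labels are permuted (group sizes preserved, pairing
#' blocks dropped under the null), every method is run on every permuted
#' copy, and the fraction of set-level p-values below each alpha is
#' reported as a percentage of all tests.
#'
#' @param datasets List of `ExpressionDataset` objects.
#' @param collection A `GeneSetCollection` (restricted per dataset
#'   internally).
#' @param methods Character vector of method ids (see [gsa_methods()]).
#' @param n_phen_perm Phenotype permutations per dataset.
#' @param alphas Significance levels at which positives are counted.
#' @param n_perm Within-analysis permutations for resampling methods.
#' @param seed Master seed; per-dataset/permutation seeds are derived from
#'   it.
#' @param min_size Minimum retained set size (see [restrict_collection()]).
#' @return Data frame with columns `method`, `alpha`, `n_tests`,
#'   `n_positive`, `fp_percent`. Per-method failures are logged and the
#'   affected cells excluded from the totals.
#' @export
phenotype_permutation_experiment <- function(datasets, collection, methods,
                                             n_phen_perm = 50,
                                             alphas = c(0.01, 0.05),
                                             n_perm = 1000, seed = 1L,
                                             min_size = 3) {
  counts <- matrix(0, length(methods), length(alphas),
                   dimnames = list(methods, as.character(alphas)))
  totals <- stats::setNames(numeric(length(methods)), methods)
  for (di in seq_along(datasets)) {
    ds <- datasets[[di]]
    set.seed(seed + 7919L * di)
    perms <- replicate(n_phen_perm, sample(ds$group))
    for (pi in seq_len(n_phen_perm)) {
      pds <- ds
      pds$group <- as.integer(perms[, pi])
      pds$block <- NULL  # labels exchangeable under the null
      pds$name <- sprintf("%s_perm%d", ds$name, pi)
      run_seed <- (seed + 104729L * di + 31L * pi) %% .Machine$integer.max
      for (m in methods) {
        res <- tryCatch(
          run_method(pds, collection, m, n_perm = n_perm,
                     seed = run_seed, min_size = min_size),
          error = function(e) {
            message(sprintf("method %s failed on %s: %s", m, pds$name,
                            conditionMessage(e)))
            NULL
          })
        if (is.null(res)) next
        totals[m] <- totals[m] + nrow(res)
        for (ai in seq_along(alphas)) {
          counts[m, ai] <- counts[m, ai] + sum(res$p_value < alphas[ai])
        }
      }
    }
  }
  out <- expand.grid(method = methods, alpha = alphas,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n_tests <- totals[out$method]
  out$n_positive <- counts[cbind(out$method, as.character(out$alpha))]
  out$fp_percent <- 100 * out$n_positive / pmax(out$n_tests, 1)
  out
}
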