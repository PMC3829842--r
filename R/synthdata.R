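# Synthetic expression data with the structure the benchmark assumes:
# block-correlated gene sets, a designated target set with partial
# (possibly bidirectional) differential expression, paired or unpaired
# two-group designs on a log2-like Gaussian scale.

#' Configuration for synthetic benchmark data
#'
#' Defaults emulate an RMA-normalized two-group microarray study: ~2000
#' genes on a log2 scale centered at 8 with sd 2, 50 gene sets of 10-100
#' genes, a 40-gene target set of which half the genes shift by `delta`
#' standard deviations in cases, and weak within-set correlation.
#'
#' @param n_genes Number of genes.
#' @param n_sets Number of gene sets (including the target).
#' @param set_size_range Size range for non-target sets.
#' @param target_size Target set size.
#' @param n_per_group Samples per group (= number of blocks when paired).
#' @param paired Paired design flag.
#' @param rho Within-set compound-symmetry correlation in `[0, 1)`.
#' @param de_fraction Fraction of target genes shifted in cases.
#' @param effect_size Shift in units of the per-gene sd (`delta`).
#' @param direction_mix Fraction of shifted genes down- rather than
#'   up-regulated (0 = fully coordinated).
#' @param baseline_mean,baseline_sd Location and scale of the log2-like
#'   baseline.
#' @param seed Integer seed.
#' @return A list of class `SynthConfig`.
#' @export
synth_config <- function(n_genes = 2000, n_sets = 50,
                         set_size_range = c(10, 100), target_size = 40,
                         n_per_group = 10, paired = FALSE, rho = 0.1,
                         de_fraction = 0.5, effect_size = 1,
                         direction_mix = 0, baseline_mean = 8,
                         baseline_sd = 2, seed = 1L) {
  stopifnot(rho >= 0, rho < 1, de_fraction >= 0, de_fraction <= 1,
            direction_mix >= 0, direction_mix <= 1,
            target_size >= set_size_range[1],
            target_size <= set_size_range[2],
            set_size_range[2] <= n_genes)
  structure(list(n_genes = n_genes, n_sets = n_sets,
                 set_size_range = set_size_range,
                 target_size = target_size, n_per_group = n_per_group,
                 paired = paired, rho = rho, de_fraction = de_fraction,
                 effect_size = effect_size, direction_mix = direction_mix,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 seed = as.integer(seed)),
            class = "SynthConfig")
}

#' Generate a synthetic gene set collection
#'
#' The target set is drawn first; the remaining sets are sampled
#' independently from the gene universe (without replacement within a
#' set), so genes overlap across sets and the gene-frequency spectrum is
#' non-degenerate -- as required by frequency-weighted statistics.
#'
#' @param cfg A [synth_config()].
#' @return List with elements `collection` (a `GeneSetCollection`) and
#'   `target_id`.
#' @export
generate_collection <- function(cfg) {
  set.seed(cfg$seed)
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  sets <- vector("list", cfg$n_sets)
  sets[[1]] <- sample(genes, cfg$target_size)
  if (cfg$n_sets > 1) {
    sizes <- sample(seq(cfg$set_size_range[1], cfg$set_size_range[2]),
                    cfg$n_sets - 1, replace = TRUE)
    for (i in seq_len(cfg$n_sets - 1)) {
      sets[[i + 1]] <- sample(genes, sizes[i])
    }
  }
  names(sets) <- c("target", sprintf("set%03d", seq_len(cfg$n_sets))[-1])
  list(collection = gene_set_collection(sets), target_id = "target")
}

#' Generate a synthetic expression dataset
#'
#' Genes within a set share a latent factor giving pairwise correlation
#' `rho` (compound symmetry; genes in several sets take the factor of
#' their first set). Cases receive a shift of `effect_size` per-gene sd
#' on a `de_fraction` subset of the target genes, with `direction_mix`
#' of the shifted genes going down instead of up. Paired designs add a
#' per-block intercept with sd `baseline_sd / 2`.
#'
#' @param cfg A [synth_config()].
#' @param collection A `GeneSetCollection` (e.g. from
#'   [generate_collection()]).
#' @param target_id Id of the target set in `collection`.
#' @param seed Optional seed override (defaults to `cfg$seed + 1`).
#' @return List with `dataset` (an `ExpressionDataset`) and `truth`
#'   (target id, shifted genes with signed effects, realized config).
#' @export
generate_dataset <- function(cfg, collection, target_id,
                             seed = cfg$seed + 1L) {
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  n <- 2L * cfg$n_per_group
  group <- rep(c(0L, 1L), each = cfg$n_per_group)
  block <- NULL
  if (cfg$paired) {
    block <- rep(sprintf("b%02d", seq_len(cfg$n_per_group)), times = 2)
  }
  # latent factor assignment: first (lowest-index) set wins
  factor_of <- rep(NA_integer_, cfg$n_genes)
  for (i in seq_along(collection$sets)) {
    ix <- match(collection$sets[[i]], genes)
    factor_of[ix[is.na(factor_of[ix])]] <- i
  }
  eps <- matrix(stats::rnorm(cfg$n_genes * n), cfg$n_genes, n)
  x <- sqrt(1 - cfg$rho) * eps
  if (cfg$rho > 0) {
    fac <- matrix(stats::rnorm(length(collection$sets) * n),
                  length(collection$sets), n)
    inset <- !is.na(factor_of)
    x[inset, ] <- x[inset, ] + sqrt(cfg$rho) * fac[factor_of[inset], ]
  }
  x <- cfg$baseline_mean + cfg$baseline_sd * x
  if (cfg$paired) {
    bint <- stats::rnorm(cfg$n_per_group, sd = cfg$baseline_sd / 2)
    x <- x + rep(bint, times = 2)[col(x)]
  }
  target_genes <- collection$sets[[target_id]]
  n_shift <- round(cfg$de_fraction * length(target_genes))
  shifted <- if (n_shift > 0) sample(target_genes, n_shift) else character()
  sign_vec <- rep(1, n_shift)
  n_down <- round(cfg$direction_mix * n_shift)
  if (n_down > 0) sign_vec[seq_len(n_down)] <- -1
  if (n_shift > 0) {
    six <- match(shifted, genes)
    shift <- cfg$effect_size * cfg$baseline_sd * sign_vec
    x[six, group == 1L] <- x[six, group == 1L] + shift
  }
  ds <- expression_dataset(x, group = group,
                           sample_ids = sprintf("s%02d", seq_len(n)),
                           feature_ids = genes, block = block,
                           name = sprintf("synth_seed%d", seed))
  truth <- list(target_id = target_id, shifted_genes = shifted,
                effect_signs = sign_vec, seed = seed, config = cfg)
  list(dataset = ds, truth = truth)
}

#' Generate a suite of null datasets
#'
#' Datasets with the effect size forced to zero but correlation structure
#' retained: the regime in which a calibrated method should find nothing.
#'
#' @param cfg A [synth_config()].
#' @param collection,target_id As in [generate_dataset()].
#' @param n_datasets Number of datasets.
#' @return List of `ExpressionDataset` objects; each truth records zero
#'   shifted genes.
#' @export
generate_null_suite <- function(cfg, collection, target_id,
                                n_datasets = 10) {
  cfg$effect_size <- 0
  cfg$de_fraction <- 0
  lapply(seq_len(n_datasets), function(i) {
    generate_dataset(cfg, collection, target_id,
                     seed = (cfg$seed + 7717L * i) %% .Machine$integer.max)
  })
}
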