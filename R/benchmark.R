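# Benchmarking framework: target-set records, sensitivity/prioritization/
# specificity metrics, robust Z combination, category assignment, overall
# ranking and scenario-stratified stability.

#' Rank of the target set as a percentage
#'
#' Sets are ordered by ascending p-value (ties averaged); the target's rank
#' is expressed as a percentage of the number of sets analyzed, so values
#' well below 50 mean the method prioritized the target.
#'
#' @param results Result data frame from [run_method()].
#' @param target_id Set id of the target.
#' @return Percentage in (0, 100].
#' @export
target_rank_pct <- function(results, target_id) {
  hit <- results$set_id == target_id
  if (!any(hit)) stop("target set '", target_id, "' absent from results")
  100 * rank(results$p_value)[hit] / nrow(results)
}

#' Collect benchmark records for one dataset
#'
#' @param results_list Named list of per-method result data frames (e.g.
#'   from [run_gsa()]).
#' @param target_id Target set id for this dataset.
#' @param dataset Dataset name.
#' @return Data frame with columns `dataset`, `method_id`, `target_p`,
#'   `target_rank_pct`.
#' @export
benchmark_records <- function(results_list, target_id, dataset) {
  do.call(rbind, lapply(names(results_list), function(m) {
    res <- results_list[[m]]
    data.frame(dataset = dataset, method_id = m,
               target_p = res$p_value[res$set_id == target_id],
               target_rank_pct = target_rank_pct(res, target_id),
               stringsAsFactors = FALSE)
  }))
}

#' Per-method benchmark metrics
#'
#' Medians of the target-set p-value (sensitivity surrogate) and rank
#' percentage (prioritization) over datasets, classical sensitivity at
#' fixed alphas, and the false-positive percentage joined from the
#' phenotype-permutation experiment.
#'
#' @param records Data frame of benchmark records (see
#'   [benchmark_records()]).
#' @param fp_table Optional output of
#'   [phenotype_permutation_experiment()]; FP at `alpha = 0.01` populates
#'   `fp_pct_1`.
#' @param alphas Levels for classical sensitivity.
#' @return Data frame with one row per method: `method_id`, `med_p`,
#'   `med_rank`, `sens_at_*`, `fp_pct_1` (NA when no fp_table).
#' @export
method_metrics <- function(records, fp_table = NULL,
                           alphas = c(0.01, 0.05)) {
  methods <- unique(records$method_id)
  out <- do.call(rbind, lapply(methods, function(m) {
    r <- records[records$method_id == m, ]
    row <- data.frame(method_id = m,
                      med_p = stats::median(r$target_p),
                      med_rank = stats::median(r$target_rank_pct),
                      stringsAsFactors = FALSE)
    for (a in alphas) {
      row[[sprintf("sens_at_%g", a)]] <- mean(r$target_p < a)
    }
    row
  }))
  out$fp_pct_1 <- NA_real_
  if (!is.null(fp_table)) {
    fp1 <- fp_table[abs(fp_table$alpha - 0.01) < 1e-12, ]
    out$fp_pct_1 <- fp1$fp_percent[match(out$method_id, fp1$method)]
  }
  out
}

#' Are the target sets relevant overall?
#'
#' One-sided Wilcoxon signed-rank tests of the per-dataset target p-values
#' against 0.5 and of the target rank percentages against 50, per method.
#'
#' @param records Benchmark records data frame.
#' @return Data frame with columns `method_id`, `p_vs_half` and
#'   `rank_vs_half`.
#' @export
overall_relevance_test <- function(records) {
  methods <- unique(records$method_id)
  if (min(table(records$method_id)) < 6) {
    stop("need at least 6 datasets per method")
  }
  do.call(rbind, lapply(methods, function(m) {
    r <- records[records$method_id == m, ]
    data.frame(
      method_id = m,
      p_vs_half = suppressWarnings(
        stats::wilcox.test(r$target_p, mu = 0.5,
                           alternative = "less")$p.value),
      rank_vs_half = suppressWarnings(
        stats::wilcox.test(r$target_rank_pct, mu = 50,
                           alternative = "less")$p.value),
      stringsAsFactors = FALSE)
  }))
}

#' Robust Z-scores
#'
#' `z = (x - median(x)) / (1.4826 * MAD)`; the normal-consistency factor
#' 1.4826 makes the scale comparable to a standard deviation and is the
#' form that reproduces published method rankings built on this transform.
#'
#' @param x Numeric vector (at least 3 values).
#' @return Vector of robust Z-scores.
#' @export
robust_z <- function(x) {
  if (length(x) < 3) stop("need at least 3 values")
  md <- stats::mad(x)  # 1.4826 * median absolute deviation
  if (md == 0) stop("MAD is zero; robust Z undefined")
  (x - stats::median(x)) / md
}

#' Assign specificity categories
#'
#' Category II collects methods whose false-positive percentage at
#' alpha = 1\% exceeds `threshold_factor` times the nominal 1\%; the rest
#' are category I. The default factor 3 separates near-nominal methods
#' (FP up to ~2.5\%) from clearly inflated ones (FP from ~4.9\%).
#'
#' @param fp_pct_1 Numeric vector of FP percentages at alpha = 1\%.
#' @param threshold_factor Inflation factor defining category II.
#' @return Character vector of `"I"` / `"II"`.
#' @export
categorize <- function(fp_pct_1, threshold_factor = 3) {
  ifelse(fp_pct_1 > threshold_factor * 1, "II", "I")
}

#' Combine metrics into a robust Z ranking
#'
#' Within each specificity category, the sensitivity surrogate (median
#' target p) and prioritization score (median rank \%) are robust
#' Z-transformed and summed; category II additionally includes the Z of
#' the FP percentage, penalizing methods that buy sensitivity with false
#' positives. Methods are ranked by ascending Z sum (rank 1 = best), ties
#' broken by lower median rank then method id.
#'
#' @param metrics Data frame from [method_metrics()] with a populated
#'   `fp_pct_1` column.
#' @param category Optional precomputed category vector; defaults to
#'   [categorize()] on `fp_pct_1`.
#' @return `metrics` augmented with `category`, `z_sens`, `z_prior`,
#'   `z_spec`, `z_sum` and `rank_in_category`.
#' @export
rank_methods <- function(metrics, category = NULL) {
  if (is.null(category)) category <- categorize(metrics$fp_pct_1)
  out <- metrics
  out$category <- category
  out$z_sens <- out$z_prior <- out$z_spec <- out$z_sum <- NA_real_
  out$rank_in_category <- NA_integer_
  for (cat in unique(category)) {
    sel <- category == cat
    if (sum(sel) < 3) stop("category ", cat, " has fewer than 3 methods")
    out$z_sens[sel] <- robust_z(out$med_p[sel])
    out$z_prior[sel] <- robust_z(out$med_rank[sel])
    zsum <- out$z_sens[sel] + out$z_prior[sel]
    if (cat == "II") {
      out$z_spec[sel] <- robust_z(out$fp_pct_1[sel])
      zsum <- zsum + out$z_spec[sel]
    }
    out$z_sum[sel] <- zsum
    ord <- order(zsum, out$med_rank[sel], out$method_id[sel])
    rk <- integer(length(ord))
    rk[ord] <- seq_along(ord)
    out$rank_in_category[sel] <- rk
  }
  out[order(out$category, out$rank_in_category), , drop = FALSE]
}

#' Scenario-stratified ranking stability
#'
#' Datasets are split on four factors -- total sample size, target set
#' size, design (paired vs unpaired) and effect size (percentage of genes
#' with nominal p < 0.05) -- at the median of each numeric factor. The
#' method ranking is recomputed within each subset and compared with the
#' overall ranking by Spearman correlation, per category.
#'
#' @param records Benchmark records data frame.
#' @param dataset_features Data frame with columns `dataset`, `n_samples`,
#'   `target_size`, `paired` (logical), `effect_pct`.
#' @param fp_table Phenotype-permutation FP table (FP rates are a property
#'   of the method, reused across subsets).
#' @param category Optional fixed category assignment (named by method).
#' @return List with `overall` (the full-data ZTable) and `scenarios`, a
#'   data frame of per-subset Spearman correlations with columns `factor`,
#'   `subset`, `cutoff`, `n_datasets`, `category`, `spearman`, `low_n`.
#' @export
scenario_rankings <- function(records, dataset_features, fp_table = NULL,
                              category = NULL) {
  overall_metrics <- method_metrics(records, fp_table)
  if (is.null(category)) {
    category <- stats::setNames(categorize(overall_metrics$fp_pct_1),
                                overall_metrics$method_id)
  }
  overall <- rank_methods(overall_metrics,
                          category[overall_metrics$method_id])
  feats <- dataset_features
  splits <- list()
  for (f in c("n_samples", "target_size", "effect_pct")) {
    cut <- stats::median(feats[[f]])
    splits[[paste0(f, "_small")]] <-
      list(factor = f, cutoff = cut, datasets = feats$dataset[feats[[f]] < cut])
    splits[[paste0(f, "_large")]] <-
      list(factor = f, cutoff = cut, datasets = feats$dataset[feats[[f]] >= cut])
  }
  splits[["paired"]] <- list(factor = "design", cutoff = NA,
                             datasets = feats$dataset[feats$paired])
  splits[["unpaired"]] <- list(factor = "design", cutoff = NA,
                               datasets = feats$dataset[!feats$paired])
  rows <- list()
  for (nm in names(splits)) {
    sp <- splits[[nm]]
    sub <- records[records$dataset %in% sp$datasets, ]
    if (nrow(sub) == 0) next
    sub_rank <- rank_methods(method_metrics(sub, fp_table),
                             category[unique(sub$method_id)])
    for (cat in unique(sub_rank$category)) {
      a <- overall[overall$category == cat, ]
      b <- sub_rank[sub_rank$category == cat, ]
      rho <- stats::cor(a$rank_in_category,
                        b$rank_in_category[match(a$method_id, b$method_id)],
                        method = "spearman")
      rows[[length(rows) + 1]] <- data.frame(
        factor = sp$factor, subset = nm, cutoff = sp$cutoff,
        n_datasets = length(unique(sub$dataset)), category = cat,
        spearman = rho, low_n = length(unique(sub$dataset)) < 3,
        stringsAsFactors = FALSE)
    }
  }
  list(overall = overall, scenarios = do.call(rbind, rows))
}

#' Spearman correlation of two rankings
#'
#' @param a,b Numeric rank vectors of equal length.
#' @return Spearman correlation coefficient.
#' @export
spearman_cor <- function(a, b) stats::cor(a, b, method = "spearman")
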