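#' Published 42-dataset benchmark summary
#'
#' Raw performance metrics of the sixteen methods from a published
#' benchmark over 42 disease microarray datasets: median target-set
#' p-value (sensitivity surrogate), median target-set rank percentage
#' (prioritization), false-positive percentage at alpha = 1\% under
#' phenotype permutation, plus the published robust Z-scores, Z sums and
#' within-category ranks. Bundled so the Z-score ranking machinery can be
#' validated against, and applied to, an established reference; the raw
#' columns (`med_p`, `med_rank`, `fp_pct_1`) are the inputs of
#' [rank_methods()].
#'
#' @return Data frame with columns `method_id`, `sampling_type`,
#'   `category`, `med_p`, `med_rank`, `fp_pct_1`, `z_sens`, `z_prior`,
#'   `z_spec`, `z_sum`, `rank_in_category`.
#' @export
reference_metrics <- function() {
  utils::read.delim(system.file("extdata", "benchmark42_metrics.tsv",
                                package = "gsabench"),
                    stringsAsFactors = FALSE)
}

#' Published scenario-stratified method ranks
#'
#' Within-category method ranks from the same published benchmark,
#' recomputed on dataset subsets: small/large sample size (median cutoff
#' 22 samples), small/large target set (median 66 genes), paired vs
#' unpaired design, and small/large effect (median 24.6\% of genes with
#' p < 0.05).
#'
#' @return Data frame with one rank column per scenario.
#' @export
reference_scenario_ranks <- function() {
  utils::read.delim(system.file("extdata", "benchmark42_scenarios.tsv",
                                package = "gsabench"),
                    stringsAsFactors = FALSE)
}
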