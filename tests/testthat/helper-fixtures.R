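# Small in-code fixtures shared across the suite.

# Gaussian dataset with an optional mean shift on `shift_genes` in cases
make_ds <- function(G = 50, n1 = 4, n0 = 4, seed = 1, paired = FALSE,
                    shift_genes = integer(), shift = 0, sd = 1, mean = 8) {
  set.seed(seed)
  n <- n1 + n0
  x <- matrix(rnorm(G * n, mean, sd), G, n)
  group <- rep(c(0L, 1L), c(n0, n1))
  if (length(shift_genes)) {
    x[shift_genes, group == 1L] <- x[shift_genes, group == 1L] + shift
  }
  block <- NULL
  if (paired) {
    stopifnot(n1 == n0)
    block <- rep(sprintf("b%d", seq_len(n1)), times = 2)
  }
  expression_dataset(x, group = group,
                     sample_ids = sprintf("s%02d", seq_len(n)),
                     feature_ids = sprintf("g%03d", seq_len(G)),
                     block = block, name = sprintf("fix_seed%d", seed))
}

# collection of `k` random sets over the dataset's genes, set1 first
make_collection <- function(ds, k = 5, size = 10, seed = 99) {
  set.seed(seed)
  sets <- lapply(seq_len(k), function(i) sample(ds$feature_ids, size))
  names(sets) <- sprintf("set%d", seq_len(k))
  gene_set_collection(sets)
}

# minimal GeneStats-like frame for functions that only need gene/p/lfc
fake_gene_stats <- function(p, lfc = rep(0, length(p)),
                            gene = sprintf("g%03d", seq_along(p))) {
  out <- data.frame(gene = gene, lfc = lfc, t = stats::qnorm(1 - p / 2),
                    p = p, s2_post = 1, stringsAsFactors = FALSE)
  out$rank_p <- rank(out$p)
  out
}
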