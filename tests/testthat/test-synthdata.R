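test_that("config validation enforces the parameter domains", {
  expect_error(synth_config(rho = 1.2))
  expect_error(synth_config(de_fraction = 1.5))
  expect_error(synth_config(target_size = 5, set_size_range = c(10, 100)))
  cfg <- synth_config()
  expect_s3_class(cfg, "SynthConfig")
  expect_equal(cfg$n_genes, 2000)
  expect_equal(cfg$n_sets, 50)
})

test_that("collections contain the target and a non-degenerate frequency spectrum", {
  cfg <- synth_config(n_genes = 400, n_sets = 20, set_size_range = c(10, 40),
                      target_size = 20, seed = 6)
  gc1 <- generate_collection(cfg)
  expect_equal(gc1$target_id, "target")
  expect_equal(length(gc1$collection$sets$target), 20)
  f <- table(unlist(gc1$collection$sets))
  expect_gt(max(f), min(f))  # PADOG weights need spread

  solo <- generate_collection(synth_config(n_genes = 100, n_sets = 1,
                                           set_size_range = c(5, 20),
                                           target_size = 10, seed = 1))
  expect_equal(names(solo$collection$sets), "target")
})

test_that("within-set correlation matches the compound-symmetry target", {
  cfg <- synth_config(n_genes = 60, n_sets = 3, set_size_range = c(2, 10),
                      target_size = 2, n_per_group = 100, rho = 0.5,
                      effect_size = 0, de_fraction = 0, seed = 12)
  gc1 <- generate_collection(cfg)
  sim <- generate_dataset(cfg, gc1$collection, gc1$target_id)
  ix <- match(gc1$collection$sets$target, sim$dataset$feature_ids)
  r <- cor(sim$dataset$expr[ix[1], ], sim$dataset$expr[ix[2], ])
  expect_lt(abs(r - 0.5), 0.1)

  # larger sample: mean within-set correlation within +/- 0.05 of rho
  cfg2 <- synth_config(n_genes = 100, n_sets = 4, set_size_range = c(10, 15),
                       target_size = 12, n_per_group = 250, rho = 0.2,
                       effect_size = 0, de_fraction = 0, seed = 13)
  gc2 <- generate_collection(cfg2)
  sim2 <- generate_dataset(cfg2, gc2$collection, gc2$target_id)
  first_set <- function(g, col) {
    for (i in seq_along(col$sets)) if (g %in% col$sets[[i]]) return(i)
    NA
  }
  cors <- unlist(lapply(seq_along(gc2$collection$sets), function(i) {
    g <- gc2$collection$sets[[i]]
    g <- g[vapply(g, first_set, 0L, col = gc2$collection) == i]
    if (length(g) < 2) return(NULL)
    cc <- cor(t(sim2$dataset$expr[match(g, sim2$dataset$feature_ids), ]))
    cc[upper.tri(cc)]
  }))
  expect_lt(abs(mean(cors) - 0.2), 0.05)
})

test_that("truth records are consistent with the construction", {
  cfg <- synth_config(n_genes = 300, n_sets = 10, set_size_range = c(10, 30),
                      target_size = 20, n_per_group = 10, effect_size = 1,
                      de_fraction = 1, direction_mix = 0.25, seed = 3)
  gc1 <- generate_collection(cfg)
  sim <- generate_dataset(cfg, gc1$collection, gc1$target_id)
  tr <- sim$truth
  expect_true(all(tr$shifted_genes %in% gc1$collection$sets$target))
  expect_equal(length(tr$shifted_genes), 20)
  expect_equal(sum(tr$effect_signs == -1), round(0.25 * 20))

  # realized group difference on up-shifted genes ~ delta * sd
  up <- tr$shifted_genes[tr$effect_signs == 1]
  ix <- match(up, sim$dataset$feature_ids)
  d <- rowMeans(sim$dataset$expr[ix, sim$dataset$group == 1]) -
    rowMeans(sim$dataset$expr[ix, sim$dataset$group == 0])
  expect_lt(abs(mean(d) - cfg$effect_size * cfg$baseline_sd), 0.5)
})

test_that("generation is reproducible and the null suite carries no signal", {
  cfg <- synth_config(n_genes = 200, n_sets = 5, set_size_range = c(5, 20),
                      target_size = 10, n_per_group = 4, seed = 8)
  gc1 <- generate_collection(cfg)
  a <- generate_dataset(cfg, gc1$collection, gc1$target_id)
  b <- generate_dataset(cfg, gc1$collection, gc1$target_id)
  expect_identical(a$dataset$expr, b$dataset$expr)

  suite <- generate_null_suite(cfg, gc1$collection, gc1$target_id,
                               n_datasets = 5)
  expect_length(suite, 5)
  expect_true(all(vapply(suite, function(s) {
    length(s$truth$shifted_genes) == 0
  }, TRUE)))
  names_ <- vapply(suite, function(s) s$dataset$name, "")
  expect_equal(anyDuplicated(names_), 0L)
})

test_that("null data with rho=0 yields uniform gene-level p-values", {
  cfg <- synth_config(n_genes = 2000, n_sets = 10, rho = 0,
                      effect_size = 0, de_fraction = 0, seed = 30)
  gc1 <- generate_collection(cfg)
  sim <- generate_dataset(cfg, gc1$collection, gc1$target_id)
  gs <- gene_stats(sim$dataset)
  expect_gt(stats::ks.test(gs$p, "punif")$p.value, 0.01)
})

test_that("paired generation adds recoverable block structure", {
  cfg <- synth_config(n_genes = 100, n_sets = 4, set_size_range = c(5, 20),
                      target_size = 10, n_per_group = 6, paired = TRUE,
                      effect_size = 0, de_fraction = 0, seed = 5)
  gc1 <- generate_collection(cfg)
  ds <- generate_dataset(cfg, gc1$collection, gc1$target_id)$dataset
  expect_true(is_paired(ds))
  # block intercepts induce positive correlation between paired samples
  d <- ds$expr[, ds$group == 1] - ds$expr[, ds$group == 0]
  within_var <- mean(apply(d, 2, var))
  across <- ds$expr[, ds$group == 1][, c(2:6, 1)] - ds$expr[, ds$group == 0]
  across_var <- mean(apply(across, 2, var))
  expect_lt(within_var, across_var)
})
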