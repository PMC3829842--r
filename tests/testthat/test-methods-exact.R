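# Exact-value checks for the set statistics, against hand-computed or
# enumerated oracles.

test_that("hypergeometric ORA matches exhaustive enumeration", {
  universe <- LETTERS[1:10]
  de <- LETTERS[1:4]
  set <- c("A", "B", "C", "E", "F")  # overlap 3 with DE
  res <- ora_test(de, universe, set)
  expect_equal(res$statistic, 3)
  expect_equal(res$p_value, 66 / 252)
  # brute force over all C(10,5) candidate sets of the same size
  draws <- utils::combn(10, 5)
  ks <- colSums(matrix(universe[draws] %in% de, nrow = 5))
  expect_equal(mean(ks >= 3), 66 / 252)

  expect_equal(ora_test(character(), universe, set)$p_value, 1)
  expect_equal(ora_test(de, universe, universe)$p_value, 1)
  expect_error(ora_test(de, character(), set), "empty universe")
})

test_that("the ORA DE-selection cascade follows its three rules in order", {
  # rule 1: >200 genes at FDR < 0.1
  p <- c(rep(1e-6, 300), runif(700, 0.5, 1))
  gs <- fake_gene_stats(p, lfc = rep(0, 1000))
  expect_setequal(ora_select_de(gs), gs$gene[1:300])

  # rule 2: rule 1 yields few, >200 pass p<0.05 & |lfc|>log2(1.5)
  set.seed(8)
  p2 <- c(rep(0.04, 250), runif(750, 0.3, 1))
  lfc2 <- c(rep(1, 250), rep(0, 750))
  gs2 <- fake_gene_stats(p2, lfc = lfc2)
  expect_setequal(ora_select_de(gs2), gs2$gene[1:250])
  # fold-change filter is on the log2 ratio scale
  gs2b <- gs2; gs2b$lfc[1:250] <- 0.5   # below log2(1.5) ~ 0.585
  expect_equal(length(ora_select_de(gs2b)), 10)  # falls through to rule 3

  # rule 3: top 1% by p
  p3 <- seq(0.06, 1, length.out = 1000)
  gs3 <- fake_gene_stats(p3)
  expect_equal(ora_select_de(gs3), gs3$gene[1:10])
})

test_that("MRGSE matches exact subset enumeration on small universes", {
  gs <- fake_gene_stats(p = c(0.01, 0.02, 0.5, 0.6, 0.7))
  res <- mean_rank_test(gs, gs$gene[1:2])  # the two smallest p
  expect_equal(res$p_value, 1 / 10)        # 1 of C(5,2) subsets

  gs10 <- fake_gene_stats(p = seq(0.01, 0.1, by = 0.01))
  expect_equal(mean_rank_test(gs10, gs10$gene[1])$p_value, 1 / 10)

  # interleaved set: mean rank equals the background's, p non-extreme
  gsl <- fake_gene_stats(p = seq(0.05, 0.5, by = 0.05))
  resl <- mean_rank_test(gsl, gsl$gene[c(2, 4, 6, 8, 10)])
  expect_gt(resl$p_value, 0.4)
  expect_lt(resl$p_value, 0.75)

  expect_error(mean_rank_test(gs, gs$gene), "background")
})

test_that("MRGSE normal approximation agrees with wilcox.test", {
  set.seed(31)
  gs <- fake_gene_stats(p = runif(60))
  ix <- c(3, 10, 22, 35, 41, 50, 59)
  res <- mean_rank_test(gs, gs$gene[ix])
  ref <- stats::wilcox.test(gs$rank_p[ix], gs$rank_p[-ix],
                            alternative = "less", exact = FALSE,
                            correct = TRUE)$p.value
  expect_equal(res$p_value, ref, tolerance = 1e-10)
})

test_that("SIGPATHWAY Q1 equals brute-force enumeration over all subsets", {
  ds <- make_ds(G = 6, n1 = 3, n0 = 3, seed = 17, shift_genes = 1:2,
                shift = 2)
  set <- ds$feature_ids[1:3]
  res <- sigpathway_test(ds, set, hypothesis = "Q1", n_perm = 25, seed = 1)
  gs <- suppressMessages(gene_stats(ds))
  draws <- utils::combn(6, 3)
  nulls <- colMeans(matrix(gs$t[draws], nrow = 3))
  obs <- mean(gs$t[1:3])
  z <- (obs - mean(nulls)) / sd(nulls)
  zn <- (nulls - mean(nulls)) / sd(nulls)
  p_brute <- (sum(abs(zn) >= abs(z)) + 1) / (length(zn) + 1)
  expect_equal(res$p_value, p_brute)
})

test_that("pre-ranked GSEA equals brute-force enumeration over all subsets", {
  ds <- make_ds(G = 6, n1 = 3, n0 = 3, seed = 23, shift_genes = 1:3,
                shift = 1.5)
  set <- ds$feature_ids[c(1, 2, 4)]
  res <- gsea_test(ds, set, method = "GSEAP", n_perm = 25, seed = 1)
  gs <- suppressMessages(gene_stats(ds))
  tv <- setNames(gs$t, gs$gene)
  es_obs <- gsea_es(tv, set)
  draws <- utils::combn(6, 3)
  es_null <- apply(draws, 2, function(ix) gsea_es(tv, gs$gene[ix]))
  pool <- if (es_obs > 0) es_null[es_null > 0] else -es_null[es_null < 0]
  p_brute <- (sum(pool >= abs(es_obs)) + 1) / (length(pool) + 1)
  expect_equal(res$p_value, p_brute)
  expect_equal(res$statistic, es_obs)
})

test_that("the enrichment score matches hand computation and its limits", {
  r <- setNames(c(4, 3, 2, 1), c("a", "b", "c", "d"))
  expect_equal(gsea_es(r, c("a", "b")), 1)       # peaks after second hit
  expect_equal(gsea_es(r, c("a", "b"), 0), 1)    # classic KS, same here
  # weight 0 equals the unweighted KS statistic computed from ECDFs
  set.seed(5)
  stats_v <- setNames(rnorm(30), sprintf("g%d", 1:30))
  set <- sprintf("g%d", sample(30, 8))
  ord <- names(sort(stats_v, decreasing = TRUE))
  hits <- cumsum(ord %in% set) / 8
  miss <- cumsum(!(ord %in% set)) / 22
  ks_brute <- (hits - miss)[which.max(abs(hits - miss))]
  expect_equal(gsea_es(stats_v, set, 0), ks_brute)
  # a set occupying the top positions attains ES = 1
  expect_equal(gsea_es(stats_v, ord[1:5]), 1)
  expect_error(gsea_es(setNames(c(0, 0, 1), c("x", "y", "z")),
                       c("x", "y")), "zero")
})

test_that("the enrichment score agrees with fgsea's implementation", {
  skip_if_not_installed("fgsea")
  set.seed(12)
  stats_v <- setNames(rnorm(100), sprintf("g%d", 1:100))
  set <- sprintf("g%d", sample(100, 10))
  sorted <- sort(stats_v, decreasing = TRUE)
  ref <- fgsea::calcGseaStat(sorted, which(names(sorted) %in% set),
                             gseaParam = 1)
  expect_equal(gsea_es(stats_v, set, 1), ref, tolerance = 1e-12)
})

test_that("maxmean takes the dominating one-sided mean with its sign", {
  expect_equal(maxmean_stat(c(2, -1, 3)), 5 / 3)
  expect_equal(maxmean_stat(c(0, 0, 0)), 0)
  expect_equal(maxmean_stat(c(-2, -2, -2)), -2)
})

test_that("PADOG weights hit the stated endpoints", {
  col <- gene_set_collection(list(
    s1 = c("a", "b", "c"), s2 = c("a", "b", "d"), s3 = c("a", "b", "e"),
    s4 = c("a", "b", "f"), s5 = c("a", "g", "h")))
  w <- padog_weights(col)
  expect_equal(unname(w["a"]), 1)       # f = f_max = 5
  expect_equal(unname(w["c"]), 2)       # f = f_min = 1 -> 1 + sqrt(1)
  expect_true(all(w >= 1 & w <= 2))

  disjoint <- gene_set_collection(list(s1 = c("a", "b"), s2 = c("c", "d")))
  expect_true(all(padog_weights(disjoint) == 1))
})

test_that("CAMERA's variance inflation follows 1 + (m-1)*rho", {
  # two genes with known sample correlation
  set.seed(2)
  x <- rnorm(20)
  y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(20)
  r <- cor(x, y)
  vf <- gsabench:::camera_vif(rbind(x, y))
  expect_equal(vf$vif, 1 + r, tolerance = 1e-12)
  # perfectly correlated set of m genes -> VIF = m
  m10 <- matrix(rep(x, 10), nrow = 10, byrow = TRUE)
  m10 <- m10 * (1 + 1e-9 * seq_len(10))  # break exact degeneracy
  expect_equal(gsabench:::camera_vif(m10)$vif, 10, tolerance = 1e-3)
})

test_that("GAGE reduces to a single comparison and obeys Stouffer scaling", {
  # one case sample: combined p equals the single-comparison p
  ds <- make_ds(G = 40, n1 = 2, n0 = 4, seed = 9, shift_genes = 1:8,
                shift = 2)
  ds1 <- ds
  keep <- c(which(ds$group == 0L), which(ds$group == 1L)[1])
  ds1$expr <- ds$expr[, keep]
  ds1$group <- ds$group[keep]
  ds1$sample_ids <- ds$sample_ids[keep]
  set <- ds$feature_ids[1:8]
  r1 <- gage_test(ds1, set)
  fc <- ds1$expr[, 5] - rowMeans(ds1$expr[, 1:4])
  tt <- t.test(fc[1:8], fc[-(1:8)])
  expect_equal(r1$p_value, tt$p.value, tolerance = 1e-9)

  # k identical case columns -> combined z = z0 * sqrt(k)
  dsk <- ds1
  dsk$expr <- cbind(ds1$expr[, 1:4], ds1$expr[, 5], ds1$expr[, 5],
                    ds1$expr[, 5], ds1$expr[, 5])
  dsk$group <- c(rep(0L, 4), rep(1L, 4))
  dsk$sample_ids <- sprintf("s%d", 1:8)
  rk <- gage_test(dsk, set)
  expect_equal(rk$statistic, r1$statistic * sqrt(4), tolerance = 1e-9)
})
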