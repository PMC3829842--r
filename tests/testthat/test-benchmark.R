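test_that("target rank percentage follows the average-tie convention", {
  res <- data.frame(set_id = sprintf("s%d", 1:259),
                    p_value = seq(0.001, 0.9, length.out = 259))
  res$set_id[13] <- "target"
  expect_equal(target_rank_pct(res, "target"), 100 * 13 / 259)

  res2 <- data.frame(set_id = c("target", "a", "b", "c"),
                     p_value = c(0.001, 0.5, 0.6, 0.7))
  expect_equal(target_rank_pct(res2, "target"), 100 / 4)

  res3 <- data.frame(set_id = sprintf("s%d", 1:10), p_value = rep(0.3, 10))
  expect_equal(target_rank_pct(res3, "s4"), 100 * (10 + 1) / 20)

  expect_error(target_rank_pct(res3, "absent"), "absent")
})

test_that("method metrics summarize records and join the FP table", {
  records <- data.frame(
    dataset = rep(c("d1", "d2", "d3"), 2),
    method_id = rep(c("A", "B"), each = 3),
    target_p = c(0.1, 0.2, 0.3, 0.01, 0.04, 0.2),
    target_rank_pct = c(10, 20, 30, 5, 15, 50))
  fp <- data.frame(method = c("A", "B"), alpha = 0.01,
                   n_tests = 100, n_positive = c(2, 6),
                   fp_percent = c(2, 6))
  mm <- method_metrics(records, fp)
  expect_equal(mm$med_p, c(0.2, 0.04))
  expect_equal(mm$med_rank, c(20, 15))
  expect_equal(mm$`sens_at_0.05`, c(0, 2 / 3))
  expect_equal(mm$fp_pct_1, c(2, 6))
})

test_that("robust Z-scores use the normalized MAD and flag degeneracy", {
  ref <- reference_metrics()
  catI <- ref[ref$category == "I", ]
  z <- robust_z(catI$med_p)
  expect_equal(z[catI$method_id == "PLAGE"], -1.47, tolerance = 0.005)
  expect_equal(z[catI$method_id == "CAMERA"], 3.43, tolerance = 0.005)
  # symmetric input centers at zero
  expect_equal(median(robust_z(c(1, 2, 3, 4, 5))), 0)
  expect_error(robust_z(c(1, 1, 1, 1, 9)), "MAD")
  expect_error(robust_z(c(1, 2)), "at least 3")
})

test_that("category assignment separates near-nominal from inflated FP", {
  expect_equal(categorize(c(2.5, 4.9, 2.0, 0.47, 37.9)),
               c("I", "II", "I", "I", "II"))
  ref <- reference_metrics()
  expect_equal(categorize(ref$fp_pct_1), ref$category)
})

test_that("rank_methods reproduces the published ranking table", {
  ref <- reference_metrics()
  zt <- rank_methods(ref[, c("method_id", "med_p", "med_rank", "fp_pct_1")],
                     category = ref$category)
  zt <- zt[match(ref$method_id, zt$method_id), ]
  expect_equal(zt$rank_in_category, ref$rank_in_category)
  # published sums at the printed precision
  for (m in c("PLAGE", "GLOBALTEST", "PADOG", "CAMERA", "GSEAP")) {
    expect_lt(abs(zt$z_sum[zt$method_id == m] -
                    ref$z_sum[ref$method_id == m]), 0.0105)
  }
  # z_spec enters category II only
  expect_true(all(is.na(zt$z_spec[zt$category == "I"])))
  expect_true(all(!is.na(zt$z_spec[zt$category == "II"])))
})

test_that("tied metrics get adjacent ranks deterministically", {
  mm <- data.frame(method_id = c("A", "B", "C", "D"),
                   med_p = c(0.1, 0.1, 0.3, 0.4),
                   med_rank = c(20, 20, 40, 50),
                   fp_pct_1 = c(1, 1, 1, 1))
  zt <- rank_methods(mm, category = rep("I", 4))
  expect_equal(zt$rank_in_category[zt$method_id %in% c("A", "B")], c(1, 2))
})

test_that("relevance tests match exact signed-rank enumeration", {
  set.seed(44)
  records <- do.call(rbind, lapply(c("M1", "M2"), function(m) {
    data.frame(dataset = sprintf("d%d", 1:8), method_id = m,
               target_p = if (m == "M1") runif(8, 0, 0.2)
                          else 0.5 + c(-0.15, 0.15, -0.1, 0.1,
                                       -0.05, 0.05, -0.2, 0.2),
               target_rank_pct = runif(8, 10, 60))
  }))
  out <- overall_relevance_test(records)
  x <- records$target_p[records$method_id == "M1"]
  # brute-force null: all 2^8 sign assignments of the |x-0.5| ranks
  r <- rank(abs(x - 0.5))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 8)))
  wnull <- signs %*% r
  wobs <- sum(r[x - 0.5 > 0])
  p_exact <- mean(wnull <= wobs)
  expect_equal(out$p_vs_half[out$method_id == "M1"], p_exact,
               tolerance = 1e-10)
  expect_lt(out$p_vs_half[out$method_id == "M1"], 0.05)
  expect_gt(out$p_vs_half[out$method_id == "M2"], 0.3)  # symmetric around 0.5

  many <- data.frame(dataset = sprintf("d%d", 1:42), method_id = "M",
                     target_p = rep(0.01, 42),
                     target_rank_pct = rep(1, 42))
  outm <- suppressWarnings(overall_relevance_test(many))
  expect_lt(outm$p_vs_half, 1e-6)
})

test_that("scenario stability recovers published and degenerate Spearman values", {
  sc <- reference_scenario_ranks()
  catI <- sc[sc$category == "I", ]
  expect_equal(round(spearman_cor(catI$overall, catI$unpaired), 2), 0.98)
  expect_equal(spearman_cor(1:12, 1:12), 1)
  expect_equal(spearman_cor(1:12, 12:1), -1)
})

test_that("scenario splits partition the datasets at their medians", {
  set.seed(3)
  methods <- c("A", "B", "C", "D")
  datasets <- sprintf("d%d", 1:8)
  records <- expand.grid(dataset = datasets, method_id = methods,
                         stringsAsFactors = FALSE)
  records$target_p <- runif(nrow(records), 0, 0.5)
  records$target_rank_pct <- runif(nrow(records), 1, 80)
  fp <- data.frame(method = methods, alpha = 0.01, n_tests = 100,
                   n_positive = c(1, 1, 2, 1),
                   fp_percent = c(1, 1, 2, 1))
  feats <- data.frame(dataset = datasets, n_samples = c(8, 8, 10, 12, 20, 24, 30, 40),
                      target_size = c(10, 20, 30, 40, 50, 60, 70, 80),
                      paired = rep(c(TRUE, FALSE), each = 4),
                      effect_pct = seq(5, 40, 5))
  out <- scenario_rankings(records, feats, fp)
  sc <- out$scenarios
  small <- sc[sc$subset == "n_samples_small" & sc$category == "I", ]
  large <- sc[sc$subset == "n_samples_large" & sc$category == "I", ]
  expect_equal(small$n_datasets + large$n_datasets, 8)
  expect_equal(small$cutoff, median(feats$n_samples))
  expect_true(all(sc$spearman >= -1 & sc$spearman <= 1))
  expect_true(all(sc$subset[sc$factor == "design"] %in%
                    c("paired", "unpaired")))
})
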