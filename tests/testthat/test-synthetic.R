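test_that("generators are pure functions of parameters and seed", {
  expect_identical(gen_essential_sets(seed = 5L), gen_essential_sets(seed = 5L))
  u <- sprintf("G%05d", 1:500)
  expect_identical(gen_de_table(u, seed = 5L), gen_de_table(u, seed = 5L))
  expect_identical(gen_expression(seed = 5L, n_background = 10L,
                                  module_sizes = c(8L, 8L, 8L)),
                   gen_expression(seed = 5L, n_background = 10L,
                                  module_sizes = c(8L, 8L, 8L)))
  expect_identical(gen_denovo(seed = 5L), gen_denovo(seed = 5L))
  expect_identical(gen_feature_table(u, seed = 5L), gen_feature_table(u, seed = 5L))
  expect_identical(gen_risk_lists(u, seed = 5L), gen_risk_lists(u, seed = 5L))
  # and different seeds give different draws
  expect_false(identical(gen_essential_sets(seed = 5L)$set_a,
                         gen_essential_sets(seed = 6L)$set_a))
})

test_that("essential-set generator hits sizes exactly and validates feasibility", {
  s <- gen_essential_sets(100L, 80L, 30L, 500L, seed = 1L)
  expect_length(s$set_a, 100L)
  expect_length(s$set_b, 80L)
  expect_length(intersect(s$set_a, s$set_b), 30L)
  disjoint <- gen_essential_sets(50L, 40L, 0L, 200L, seed = 2L)
  expect_length(intersect(disjoint$set_a, disjoint$set_b), 0L)
  equal <- gen_essential_sets(30L, 30L, 30L, 100L, seed = 3L)
  expect_setequal(equal$set_a, equal$set_b)
  expect_error(gen_essential_sets(10L, 10L, 11L, 100L), "smaller set")
  expect_error(gen_essential_sets(100L, 100L, 0L, 150L), "universe too small")
})

test_that("null DE tables carry uniform p-values; planted tables shift one direction", {
  u <- sprintf("G%05d", 1:5000)
  de0 <- gen_de_table(u, seed = 21L)
  ks <- stats::ks.test(de0$table$pvalue, "punif")
  expect_gt(ks$p.value, 0.01)
  # roughly balanced fold-change signs, none exactly zero
  expect_true(all(de0$table$log2fc != 0))
  expect_gt(mean(de0$table$log2fc > 0), 0.45)
  expect_lt(mean(de0$table$log2fc > 0), 0.55)

  target <- u[1:1000]
  de1 <- gen_de_table(u, target_set = target, direction = "down",
                      delta = delta_for_cohens_d(0.8), seed = 22L)
  expect_equal(de1$truth$implied_d, 0.8)
  sl <- split_by_direction(de1$table)
  in_t <- sl$down$score[sl$down$gene %in% target]
  out_t <- sl$down$score[!sl$down$gene %in% target]
  expect_gt(mean(in_t) - mean(out_t), 0.5 * delta_for_cohens_d(0.8))
  # up direction untouched
  up_in <- sl$up$score[sl$up$gene %in% target]
  up_out <- sl$up$score[!sl$up$gene %in% target]
  expect_lt(abs(mean(up_in) - mean(up_out)), 0.1)
  expect_error(gen_de_table(u, target_set = "NOT_THERE"), "subset")
})

test_that("noise-free expression recovers templates exactly; metadata permutes safely", {
  sim <- gen_expression(module_sizes = c(20L),
                        pattern_labels = "prenatal_high_drop",
                        n_background = 0L, snr = 1e6, seed = 31L)
  asg <- structure(sim$truth$assignment, class = "module_assignment")
  eg <- module_eigengene(sim$expr, asg, 1L)
  expect_gt(abs(stats::cor(eg$scores, sim$truth$templates[, 1])), 0.9999)
  # shuffling samples together with metadata leaves downstream labels unchanged
  perm <- sample(ncol(sim$expr$values))
  shuffled <- expression_matrix(sim$expr$values[, perm],
                                sim$expr$age_pcd[perm], sim$expr$prenatal[perm])
  p1 <- classify_temporal_pattern(eg$scores, sim$expr$age_pcd, sim$expr$prenatal)
  eg2 <- module_eigengene(shuffled, asg, 1L)
  p2 <- classify_temporal_pattern(eg2$scores, shuffled$age_pcd, shuffled$prenatal)
  expect_identical(p1$pattern, p2$pattern)
})

test_that("de novo generator rejects bad inputs and plants the requested factor", {
  expect_error(gen_denovo(n_trios = 0L), "n_trios")
  big <- gen_denovo(gamma = 10, seed = 41L)
  expect_gt(big$observed[["lof"]], 5 * big$truth$lambda_null[["lof"]] / 2)
  expect_equal(denovo_expected(big$rates, big$set, "lof", big$n_trios),
               unname(big$truth$lambda_null[["lof"]]))
})

test_that("risk-list generator approximates the planted odds ratio", {
  u <- sprintf("G%05d", 1:20000)
  target <- u[1:3000]
  risk <- gen_risk_lists(u, target, odds_ratio = 5, baseline_rate = 0.02,
                         seed = 51L)
  members <- risk$categories$gene
  a <- sum(target %in% members)
  b <- length(target) - a
  cc <- sum(!members %in% target)
  d <- length(u) - a - b - cc
  or_hat <- (a * d) / (b * cc)
  expect_gt(or_hat, 3.5)
  expect_lt(or_hat, 7)
})

test_that("the end-to-end benchmark recovers every planted signal", {
  bm <- suppressMessages(run_synthetic_benchmark(seed = 123L, n_perm = 100L))
  expect_identical(c(bm$partition$a_specific, bm$partition$b_specific,
                     bm$partition$shared), c(3140L, 1451L, 698L))
  expect_lt(abs(bm$recovered_d - bm$planted_d), 0.1)
  expect_lte(bm$permutation$empirical_quantile, 0.01)
  expect_gte(bm$module_ari, 0.8)
  expect_identical(bm$patterns_recovered, 3L)
  expect_lt(bm$denovo$p[[1]], 0.05)
  expect_lt(bm$feature$p_wilcoxon, 0.01)
  expect_true(bm$risk_enrichment$significant[[1]])
})
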