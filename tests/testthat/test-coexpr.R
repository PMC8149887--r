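test_that("signed adjacency maps correlation endpoints correctly", {
  # two perfectly correlated genes, two anti-correlated
  m <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8), g3 = -c(1, 2, 3, 4))
  a <- signed_adjacency(m, beta = 15)
  expect_equal(a["g1", "g2"], 1)
  expect_equal(a["g1", "g3"], 0)
  # uncorrelated pair at beta = 15 sits at 0.5^15
  m2 <- rbind(g1 = c(1, -1, 1, -1), g2 = c(1, 1, -1, -1))
  a2 <- signed_adjacency(m2, beta = 15)
  expect_equal(a2["g1", "g2"], 0.5^15)
  expect_error(signed_adjacency(m, beta = 0), "beta")
})

test_that("biweight midcorrelation resists a gross outlier", {
  withr::with_seed(42, {
    x <- rnorm(60)
    y <- x + rnorm(60, sd = 0.1)
    y[1] <- 60 # one corrupted sample
    m <- rbind(g1 = x, g2 = y)
    a_p <- signed_adjacency(m, beta = 1, method = "pearson")
    a_b <- signed_adjacency(m, beta = 1, method = "biweight")
    # recover correlation on the a = (1 + r)/2 scale
    expect_gt(2 * a_b["g1", "g2"] - 1, 0.9)
    expect_lt(2 * a_p["g1", "g2"] - 1, 2 * a_b["g1", "g2"] - 1)
  })
})

test_that("topological overlap matches the formula on trivial and random inputs", {
  # two genes fully connected: TOM = 1
  a <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_equal(topological_overlap(a)[1, 2], 1)
  # disconnected pair with no shared neighbors: TOM = 0
  a0 <- diag(2)
  expect_equal(topological_overlap(a0)[1, 2], 0)
  withr::with_seed(17, {
    for (n in c(5, 20)) {
      adj <- random_symmetric_adjacency(n)
      expect_lt(max(abs(topological_overlap(adj) - naive_tom(adj))), 1e-10)
    }
  })
  expect_error(topological_overlap(matrix(c(1, 2, 0, 1), 2, 2)), "symmetric")
})

test_that("adjacency and TOM are permutation-equivariant", {
  withr::with_seed(23, {
    sim <- gen_expression(module_sizes = c(10L, 8L),
                          pattern_labels = c("prenatal_rise_sustained",
                                             "prenatal_high_drop"),
                          n_prenatal = 6L, n_postnatal = 6L, n_background = 5L,
                          seed = 23L)
    m <- sim$expr$values
    perm <- sample(nrow(m))
    a1 <- signed_adjacency(m, beta = 6)
    a2 <- signed_adjacency(m[perm, ], beta = 6)
    expect_equal(a2, a1[perm, perm])
    expect_equal(topological_overlap(a2), topological_overlap(a1)[perm, perm])
  })
})

test_that("module detection recovers planted blocks and respects the size rule", {
  sim <- gen_expression(module_sizes = c(40L, 40L, 40L), seed = 6L,
                        n_background = 60L)
  tom <- topological_overlap(signed_adjacency(sim$expr))
  det <- detect_modules(tom, min_module_size = 30L)
  ari <- adjusted_rand_index(sim$truth$assignment,
                             unclass(det)[names(sim$truth$assignment)])
  expect_gte(ari, 0.8)
  # a 10-gene block is below the minimum size and must stay unassigned
  sim_small <- gen_expression(module_sizes = c(40L, 10L),
                              pattern_labels = c("prenatal_rise_sustained",
                                                 "prenatal_high_drop"),
                              n_background = 40L, seed = 7L)
  tom_s <- topological_overlap(signed_adjacency(sim_small$expr))
  det_s <- detect_modules(tom_s, min_module_size = 30L)
  small_genes <- names(sim_small$truth$assignment)[sim_small$truth$assignment == 2]
  expect_true(all(unclass(det_s)[small_genes] == 0L))
})

test_that("pure-noise expression yields no modules", {
  hits <- vapply(1:5, function(s) {
    sim <- gen_expression(module_sizes = integer(0), pattern_labels = character(0),
                          n_background = 80L, seed = s)
    tom <- topological_overlap(signed_adjacency(sim$expr))
    det <- suppressWarnings(detect_modules(tom))
    length(attr(det, "sizes"))
  }, integer(1))
  expect_true(mean(hits == 0L) > 0.5)
})

test_that("eigengene has unit norm, positive orientation and recovers templates", {
  sim <- gen_expression(module_sizes = c(30L),
                        pattern_labels = "prenatal_rise_sustained",
                        n_background = 0L, snr = 3, seed = 31L)
  assignment <- structure(sim$truth$assignment, class = "module_assignment")
  eg <- module_eigengene(sim$expr, assignment, 1L)
  expect_equal(sum(eg$scores^2), 1)
  z <- t(scale(t(sim$expr$values)))
  expect_gte(stats::cor(eg$scores, colMeans(z)), 0)
  # correlation with the planted template (sample order is age-sorted already)
  expect_gte(abs(stats::cor(eg$scores, sim$truth$templates[, 1])), 0.9)
  # flipping all genes flips the raw PC but orientation restores the sign
  flipped <- expression_matrix(-sim$expr$values, sim$expr$age_pcd, sim$expr$prenatal)
  eg_f <- module_eigengene(flipped, assignment, 1L)
  zf <- t(scale(t(flipped$values)))
  expect_gte(stats::cor(eg_f$scores, colMeans(zf)), 0)
  # identical genes: eigengene correlates perfectly with the shared profile
  m <- rbind(a = c(1, 2, 3, 4, 2), b = c(1, 2, 3, 4, 2), c = c(1, 2, 3, 4, 2))
  colnames(m) <- paste0("s", 1:5)
  asg <- structure(stats::setNames(rep(1L, 3), rownames(m)),
                   class = "module_assignment")
  egi <- module_eigengene(m, asg, 1L)
  expect_equal(abs(stats::cor(egi$scores, m[1, ])), 1)
  expect_equal(egi$var_explained, 1)
})

test_that("module merging reaches a fixpoint driven by eigengene correlation", {
  # two identical planted trajectories must merge into one module
  sim <- gen_expression(module_sizes = c(35L, 35L),
                        pattern_labels = c("prenatal_rise_sustained",
                                           "prenatal_rise_sustained"),
                        n_background = 0L, snr = 5, seed = 41L)
  asg <- structure(sim$truth$assignment, class = "module_assignment")
  merged <- merge_modules(sim$expr, asg, merge_threshold = 0.9)
  expect_length(attr(merged, "sizes"), 1L)
  # three mutually similar modules collapse to a single one
  sim3 <- gen_expression(module_sizes = c(30L, 30L, 30L),
                         pattern_labels = rep("prenatal_high_drop", 3),
                         n_background = 0L, snr = 5, seed = 43L)
  asg3 <- structure(sim3$truth$assignment, class = "module_assignment")
  merged3 <- merge_modules(sim3$expr, asg3, merge_threshold = 0.9)
  expect_length(attr(merged3, "sizes"), 1L)
  # dissimilar trajectories stay apart
  simd <- gen_expression(module_sizes = c(30L, 30L),
                         pattern_labels = c("prenatal_rise_sustained",
                                            "prenatal_high_drop"),
                         n_background = 0L, snr = 5, seed = 44L)
  asgd <- structure(simd$truth$assignment, class = "module_assignment")
  expect_length(attr(merge_modules(simd$expr, asgd, 0.9), "sizes"), 2L)
})

test_that("temporal patterns classify the three canonical trajectories", {
  age <- c(60, 100, 150, 200, 230, 260, 400, 2000, 10000)
  prenatal <- age < 266
  rise <- c(-1, -0.6, -0.2, 0.2, 0.6, 1, 1, 1, 1)
  drop <- -rise
  lowmid <- c(rep(-1, 6), 0, 0, 0)
  expect_identical(classify_temporal_pattern(rise, age, prenatal)$pattern,
                   "prenatal_rise_sustained")
  expect_identical(classify_temporal_pattern(drop, age, prenatal)$pattern,
                   "prenatal_high_drop")
  expect_identical(classify_temporal_pattern(lowmid, age, prenatal)$pattern,
                   "low_prenatal_mid")
  # a birth-peaked trajectory matches none of the three patterns
  peak <- c(-1, -0.5, 0, 0.5, 1, 1.5, -1, -1, -1)
  expect_identical(classify_temporal_pattern(peak, age, prenatal)$pattern,
                   "unclassified")
  expect_error(classify_temporal_pattern(rise[1:4], age[1:4], prenatal[1:4]),
               "prenatal")
})

test_that("full pipeline recovers modules and patterns on the synthetic preset", {
  ok <- vapply(1:4, function(s) {
    sim <- gen_expression(seed = s)
    fit <- suppressMessages(run_coexpression(sim$expr))
    ari <- adjusted_rand_index(sim$truth$assignment,
                               unclass(fit$assignment)[names(sim$truth$assignment)])
    ari >= 0.8 && all(sort(unique(sim$truth$patterns)) %in% fit$patterns$pattern)
  }, logical(1))
  expect_gte(sum(ok), 3L)
})

test_that("in-package adjusted Rand index agrees with the reference implementation", {
  skip_if_not_installed("mclust")
  withr::with_seed(55, {
    for (i in 1:10) {
      a <- sample(0:3, 60, replace = TRUE)
      b <- sample(0:3, 60, replace = TRUE)
      expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
    }
  })
})
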