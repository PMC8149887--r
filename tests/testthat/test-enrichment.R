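test_that("Fisher's exact test matches hand examples and handles degenerate tables", {
  expect_equal(fisher_exact(c(3, 1, 1, 3), "greater")$p, 17 / 70)
  expect_equal(fisher_exact(c(3, 1, 1, 3))$odds_ratio, 9)
  expect_gt(fisher_exact(c(5, 5, 5, 5), "greater")$p, 0.5)
  degenerate <- fisher_exact(c(0, 0, 3, 4), "greater")
  expect_equal(degenerate$p, 1)
  expect_true(is.na(degenerate$odds_ratio))
  expect_true(is.infinite(fisher_exact(c(3, 0, 1, 3))$odds_ratio))
  expect_error(fisher_exact(c(-1, 1, 1, 1)), "non-negative")
})

test_that("Fisher p equals the fixed-margins enumeration oracle", {
  withr::with_seed(61, {
    for (i in 1:40) {
      ct <- random_2x2(40)
      for (side in c("greater", "two-sided")) {
        expect_equal(fisher_exact(ct, side)$p,
                     enum_fisher_p(ct[1], ct[2], ct[3], ct[4], side),
                     tolerance = 1e-12)
      }
      # p-values also agree with the reference implementation
      mat <- matrix(ct, 2, 2, byrow = TRUE)
      expect_equal(fisher_exact(ct, "greater")$p,
                   stats::fisher.test(mat, alternative = "greater")$p.value,
                   tolerance = 1e-10)
      expect_equal(fisher_exact(ct, "two-sided")$p,
                   stats::fisher.test(mat)$p.value, tolerance = 1e-10)
    }
  })
})

test_that("BH adjustment reproduces the step-up hand example and its contracts", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  withr::with_seed(62, {
    p <- runif(50)
    q <- bh_adjust(p)
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    # q is non-decreasing in the rank of p
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  })
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("set enrichment flags a planted category and ranks an identical one first", {
  universe <- sprintf("u%04d", 1:2000)
  query <- universe[1:150]
  categories <- list(
    planted = c(universe[1:60], universe[1900:1950]),
    null_a = universe[300:500],
    null_b = universe[600:800],
    itself = query
  )
  expect_message(
    res <- set_enrichment(c(query, "not_in_universe"), categories, universe),
    "outside the universe"
  )
  expect_true(res$significant[res$category == "planted"])
  expect_identical(res$category[which.min(res$p)], "itself")
  expect_equal(res$in_set_in_cat[res$category == "itself"], 150)
  # counts always sum to the universe
  expect_true(all(rowSums(res[, c("in_set_in_cat", "in_set_out",
                                  "out_in_cat", "out_out")]) == 2000))
  expect_error(set_enrichment(query, categories, character(0)), "universe")
})

test_that("uniform random queries are false-flagged at most at the FDR level", {
  universe <- sprintf("u%04d", 1:2000)
  categories <- lapply(stats::setNames(1:10, paste0("c", 1:10)), function(i) {
    universe[((i - 1) * 150 + 1):(i * 150)]
  })
  flagged <- withr::with_seed(63, {
    vapply(1:120, function(i) {
      any(set_enrichment(sample(universe, 100), categories, universe)$significant)
    }, logical(1))
  })
  # BH controls FDR, hence familywise false flags under the global null
  expect_lte(mean(flagged), 0.05 + 2 * sqrt(0.05 * 0.95 / 120))
})

test_that("de novo expectation is the stated arithmetic and scales linearly", {
  rates <- data.frame(gene = c("a", "b", "c"),
                      p_lof = c(4e-5, 6e-5, 1e-5),
                      p_protein_altering = c(1e-5, 2e-5, 3e-5))
  expect_equal(denovo_expected(rates, c("a", "b"), "lof", 1000), 0.2)
  expect_equal(denovo_expected(rates, character(0), "lof", 1000), 0)
  expect_equal(denovo_expected(rates, c("a", "b"), "lof", 2000),
               2 * denovo_expected(rates, c("a", "b"), "lof", 1000))
  expect_message(denovo_expected(rates, c("a", "zz"), "lof", 100), "absent")
  expect_error(denovo_expected(rates, "a", "lof", 0), "positive")
})

test_that("Poisson burden test matches the closed form and its edge cases", {
  expect_equal(denovo_test(2, 0.2), 1 - exp(-0.2) * (1 + 0.2), tolerance = 1e-12)
  expect_equal(denovo_test(0, 5), 1)
  expect_equal(denovo_test(1, 0), 0)
  expect_error(denovo_test(-1, 1), "observed")
})

test_that("planted de novo enrichment is detected and the null test is conservative", {
  p_alt <- vapply(1:150, function(s) {
    denovo_burden(gen_denovo(gamma = 3, seed = s))$p[[1]]
  }, numeric(1))
  p_null <- vapply(1:150, function(s) {
    denovo_burden(gen_denovo(gamma = 1, seed = 5000 + s))$p[[1]]
  }, numeric(1))
  expect_gte(mean(p_alt < 0.05), 0.85)
  expect_lte(mean(p_null < 0.05), 0.08)
  # discrete upper-tail p-values are super-uniform: P(p <= t) <= t (+ MC noise)
  for (t in c(0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(p_null <= t), t + 2 * sqrt(t * (1 - t) / 150))
  }
})
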