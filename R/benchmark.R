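# End-to-end simulate -> analyze -> score-against-truth run exercising every
# pipeline stage on one seed.

#' Run the full pipeline on synthetic data and score it against the truth
#'
#' Generates every input the pipeline consumes (essential sets with the
#' screen-list shape, a DE table with a planted directional effect, a
#' developmental expression matrix with three planted temporal modules, a
#' de novo model, a feature table and a risk list), analyzes each with the
#' corresponding module, and reports recovery scores against the planted
#' ground truth.
#'
#' @param seed Integer seed driving all generators.
#' @param effect_d Planted Cohen's d for the DE comparison.
#' @param direction Fold-change direction carrying the planted effect.
#' @param denovo_gamma Planted de novo enrichment factor.
#' @param feature_shift Planted latent shift of the feature table.
#' @param risk_odds_ratio Planted odds ratio of the risk list.
#' @param n_perm Permutations for the size-matched null.
#' @param config An [ess_config()] supplying the analysis constants.
#' @return A list of class `ess_benchmark` with per-stage results and
#'   recovery scores.
#' @export
run_synthetic_benchmark <- function(seed = 1L, effect_d = 0.3,
                                    direction = "down", denovo_gamma = 3,
                                    feature_shift = 0.5, risk_odds_ratio = 5,
                                    n_perm = 1000L,
                                    config = ess_config(seed = seed)) {
  seed <- check_count(seed, "seed")

  sets <- gen_essential_sets(seed = seed)
  part <- partition_sets(sets$set_a, sets$set_b, names = c("NEG", "ACEG"))

  de <- gen_de_table(sets$universe, target_set = part$a_specific,
                     direction = direction,
                     delta = delta_for_cohens_d(effect_d), seed = seed + 1L)
  slices <- split_by_direction(de$table, p_column = config$p_column,
                               neglog10_floor = config$neglog10_floor)
  slice <- slices[[direction]]
  cmp <- compare_gene_sets(slice, part$a_specific, part$b_specific,
                           set_names = c("NEG", "ACEG"))
  pool <- setdiff(sets$universe, union(sets$set_a, sets$set_b))
  null <- permutation_null(slice, pool, size_y = cmp$n_y, size_x = cmp$n_x,
                           n_perm = n_perm, seed = seed + 2L,
                           observed_p = cmp$p_wilcoxon)

  sim_expr <- gen_expression(snr = 3, seed = seed + 3L)
  fit <- run_coexpression(sim_expr$expr,
                          beta = config$soft_power,
                          min_module_size = config$min_module_size,
                          merge_threshold = config$merge_threshold)
  ari <- adjusted_rand_index(sim_expr$truth$assignment,
                             unclass(fit$assignment)[names(sim_expr$truth$assignment)])
  patterns_recovered <- if (is.null(fit$patterns)) 0L else {
    sum(sort(unique(sim_expr$truth$patterns)) %in% fit$patterns$pattern)
  }

  dn <- gen_denovo(gamma = denovo_gamma, seed = seed + 4L)
  dn_res <- denovo_burden(dn)

  feats <- gen_feature_table(sets$universe, target_set = part$a_specific,
                             shift = feature_shift, seed = seed + 5L)
  feat_cmp <- compare_feature(feats$table, part$a_specific, part$b_specific,
                              "gims", set_names = c("NEG", "ACEG"))

  risk <- gen_risk_lists(sets$universe, target_set = part$a_specific,
                         odds_ratio = risk_odds_ratio, seed = seed + 6L)
  enr <- set_enrichment(part$a_specific, risk$categories, sets$universe,
                        sidedness = config$fisher_sidedness,
                        alpha = config$alpha)

  structure(
    list(seed = seed,
         partition = summary(part),
         de_comparison = cmp,
         permutation = null,
         planted_d = effect_d,
         recovered_d = cmp$d,
         coexpression = fit,
         module_ari = ari,
         patterns_recovered = patterns_recovered,
         denovo = dn_res,
         feature = feat_cmp,
         risk_enrichment = enr),
    class = "ess_benchmark"
  )
}

#' @export
print.ess_benchmark <- function(x, ...) {
  cat(sprintf("synthetic benchmark (seed %d)\n", x$seed))
  cat(sprintf("  partition: %d / %d / %d (A-specific / B-specific / shared)\n",
              x$partition$a_specific, x$partition$b_specific, x$partition$shared))
  cat(sprintf("  DE effect: planted d = %.3f, recovered d = %.3f, Wilcoxon p = %.3g\n",
              x$planted_d, x$recovered_d, x$de_comparison$p_wilcoxon))
  cat(sprintf("  permutation empirical quantile = %.4g\n",
              x$permutation$empirical_quantile))
  cat(sprintf("  module recovery ARI = %.3f; %d/3 temporal patterns recovered\n",
              x$module_ari, x$patterns_recovered))
  cat(sprintf("  de novo p (lof / protein-altering) = %.3g / %.3g\n",
              x$denovo$p[[1]], x$denovo$p[[2]]))
  cat(sprintf("  feature `gims` d = %.3f (p = %.3g)\n",
              x$feature$d, x$feature$p_wilcoxon))
  cat(sprintf("  risk list q = %.3g (%ssignificant)\n",
              x$risk_enrichment$q[[1]],
              if (x$risk_enrichment$significant[[1]]) "" else "not "))
  invisible(x)
}
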