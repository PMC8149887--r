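# Directional comparison of -log10 p-value distributions between two gene
# sets, with a size-matched permutation null drawn from nonessential genes.
#
# This is the package's core statistic: DE tables are split by fold-change
# direction, each gene's p-value is mapped to -log10(p) (floored at a
# configurable smallest representable p), and within each direction the two
# set-specific gene groups are compared by a two-sided Wilcoxon rank-sum
# test plus pooled-SD Cohen's d. Genes belonging to both sets are excluded
# from both groups. Calibration comes from repeatedly drawing size-matched
# random gene pairs from the nonessential pool.

#' Split a DE table into up- and down-regulated slices
#'
#' Genes with positive log2 fold change go to the `up` slice, negative to
#' `down`; genes with zero or missing fold change, or a missing selected
#' p-value, are excluded with counts logged by reason. Scores are
#' `-log10(p)` with p floored at `neglog10_floor`, so p = 0 maps to 300 at
#' the default floor of 1e-300.
#'
#' @param table DE data.frame as returned by [read_de_table()].
#' @param p_column `"raw"` or `"adjusted"`.
#' @param neglog10_floor Smallest representable p.
#' @return A list of class `de_slices` with elements `up` and `down` (each a
#'   `de_slice` data.frame with columns `gene`, `score`) and `excluded`
#'   (named counts).
#' @export
split_by_direction <- function(table, p_column = c("raw", "adjusted"),
                               neglog10_floor = 1e-300) {
  p_column <- match.arg(p_column)
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop("`table` must be a non-empty data.frame", call. = FALSE)
  }
  check_number(neglog10_floor, "neglog10_floor", min = .Machine$double.xmin, max = 1)
  p <- if (p_column == "raw") table$pvalue else table$padj
  missing_p <- is.na(p)
  missing_fc <- !missing_p & is.na(table$log2fc)
  zero_fc <- !missing_p & !missing_fc & table$log2fc == 0
  keep <- !(missing_p | missing_fc | zero_fc)
  excluded <- c(missing_p = sum(missing_p), missing_fc = sum(missing_fc),
                zero_fc = sum(zero_fc))
  if (any(excluded > 0L)) {
    ess_log("excluded %d gene(s): %s", sum(excluded),
            paste(names(excluded), excluded, sep = "=", collapse = ", "))
  }
  score <- -log10(pmax(p[keep], neglog10_floor))
  gene <- table$gene[keep]
  up_idx <- table$log2fc[keep] > 0
  make_slice <- function(idx, direction) {
    structure(data.frame(gene = gene[idx], score = score[idx],
                         stringsAsFactors = FALSE),
              direction = direction, class = c("de_slice", "data.frame"))
  }
  up <- make_slice(up_idx, "up")
  down <- make_slice(!up_idx, "down")
  if (nrow(up) == 0L && nrow(down) == 0L) {
    stop("no genes left after exclusions; both slices are empty", call. = FALSE)
  }
  structure(list(up = up, down = down, excluded = excluded), class = "de_slices")
}

#' Compare the score distributions of two gene sets within one slice
#'
#' Restricts the slice to genes belonging to exactly one of the two sets
#' (shared genes are excluded from both groups), then runs the two-sided
#' Wilcoxon rank-sum test and pooled-SD Cohen's d on the `-log10(p)` scores.
#' Positive `d` means `set_y` shows stronger differential expression.
#'
#' @param slice A `de_slice` from [split_by_direction()].
#' @param set_y,set_x Character vectors of gene identifiers; `set_y` is the
#'   first group of the comparison.
#' @param set_names Length-2 labels for reporting.
#' @return An object of class `de_comparison` carrying the direction, group
#'   sizes, means, SDs, pooled SD, Cohen's `d`, rank-sum `W` and the
#'   two-sided `p_wilcoxon`.
#' @export
compare_gene_sets <- function(slice, set_y, set_x, set_names = c("Y", "X")) {
  stopifnot(inherits(slice, "de_slice"))
  shared <- intersect(set_y, set_x)
  y_genes <- setdiff(set_y, shared)
  x_genes <- setdiff(set_x, shared)
  y <- slice$score[slice$gene %in% y_genes]
  x <- slice$score[slice$gene %in% x_genes]
  if (length(y) < 2L) {
    stop(sprintf("set `%s` has %d gene(s) in the %s slice; need >= 2",
                 set_names[[1]], length(y), attr(slice, "direction")), call. = FALSE)
  }
  if (length(x) < 2L) {
    stop(sprintf("set `%s` has %d gene(s) in the %s slice; need >= 2",
                 set_names[[2]], length(x), attr(slice, "direction")), call. = FALSE)
  }
  wt <- wilcoxon_rank_sum(y, x)
  cd <- cohens_d_pooled(y, x)
  structure(
    c(list(direction = attr(slice, "direction"), set_names = set_names,
           W = wt$W, p_wilcoxon = wt$p, test_method = wt$method), cd),
    class = "de_comparison"
  )
}

#' @export
print.de_comparison <- function(x, ...) {
  cat(sprintf("DE score comparison (%s-regulated genes): %s vs %s\n",
              x$direction, x$set_names[[1]], x$set_names[[2]]))
  cat(sprintf("  n = %d vs %d; mean -log10 p = %.4f vs %.4f\n",
              x$n_y, x$n_x, x$mean_y, x$mean_x))
  cat(sprintf("  Cohen's d (pooled SD) = %.4f\n", x$d))
  cat(sprintf("  Wilcoxon W = %.0f, two-sided p = %.4g (%s)\n",
              x$W, x$p_wilcoxon, x$test_method))
  invisible(x)
}

#' @export
as.data.frame.de_comparison <- function(x, ...) {
  data.frame(direction = x$direction,
             set_y = x$set_names[[1]], set_x = x$set_names[[2]],
             n_y = x$n_y, n_x = x$n_x,
             mean_y = x$mean_y, mean_x = x$mean_x,
             sd_y = x$sd_y, sd_x = x$sd_x, sd_pooled = x$sd_pooled,
             d = x$d, W = x$W, p_wilcoxon = x$p_wilcoxon,
             stringsAsFactors = FALSE)
}

#' Size-matched permutation null for the set comparison
#'
#' Repeatedly samples two disjoint random gene sets of the observed sizes
#' from the nonessential pool (genes in the slice belonging to neither
#' essential set), reruns the Wilcoxon comparison and stores the p-value.
#' Used as a negative control: with no essentiality signal the null
#' p-values are approximately uniform, and a real comparison can be placed
#' on this distribution via its empirical quantile.
#'
#' @param slice A `de_slice`.
#' @param pool Character vector of nonessential gene identifiers; only its
#'   intersection with the slice is used.
#' @param size_y,size_x Sizes of the two random sets (match the observed
#'   comparison's group sizes).
#' @param n_perm Number of permutations.
#' @param seed Integer seed; same seed gives identical draws.
#' @param observed_p Optional p-value of the real comparison, placed on the
#'   null as `empirical_quantile = mean(null <= observed_p)`.
#' @param keep_draws Keep the sampled gene sets (for diagnostics; memory
#'   grows with `n_perm`).
#' @return An object of class `permutation_null` with `null_pvalues`,
#'   `observed_p`, `empirical_quantile`, `seed`, and optionally `draws`.
#' @export
permutation_null <- function(slice, pool, size_y, size_x, n_perm = 1000L,
                             seed = 1L, observed_p = NULL, keep_draws = FALSE) {
  stopifnot(inherits(slice, "de_slice"))
  size_y <- check_count(size_y, "size_y", min = 2L)
  size_x <- check_count(size_x, "size_x", min = 2L)
  n_perm <- check_count(n_perm, "n_perm", min = 1L)
  seed <- check_count(seed, "seed")
  scores <- slice$score[slice$gene %in% pool]
  genes <- slice$gene[slice$gene %in% pool]
  n_pool <- length(scores)
  if (n_pool < size_y + size_x) {
    stop(sprintf("nonessential pool too small: need %d, available %d",
                 size_y + size_x, n_pool), call. = FALSE)
  }
  draws <- if (keep_draws) vector("list", n_perm) else NULL
  null_p <- numeric(n_perm)
  withr::with_seed(seed, {
    for (i in seq_len(n_perm)) {
      idx <- sample.int(n_pool, size_y + size_x)
      yi <- idx[seq_len(size_y)]
      xi <- idx[-seq_len(size_y)]
      null_p[[i]] <- wilcoxon_rank_sum(scores[yi], scores[xi])$p
      if (keep_draws) draws[[i]] <- list(y = genes[yi], x = genes[xi])
    }
  })
  eq <- if (is.null(observed_p)) NA_real_ else mean(null_p <= observed_p)
  structure(
    list(null_pvalues = null_p, observed_p = observed_p,
         empirical_quantile = eq, seed = seed, n_perm = n_perm, draws = draws),
    class = "permutation_null"
  )
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("permutation null: %d size-matched draws (seed %d)\n",
              x$n_perm, x$seed))
  cat(sprintf("  null p quartiles: %s\n",
              paste(signif(stats::quantile(x$null_pvalues, c(.25, .5, .75)), 3),
                    collapse = " / ")))
  if (!is.null(x$observed_p)) {
    cat(sprintf("  observed p = %.4g, empirical quantile = %.4g\n",
                x$observed_p, x$empirical_quantile))
  }
  invisible(x)
}

#' QQ plot of the permutation null against the uniform distribution
#'
#' @param x A `permutation_null`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.permutation_null <- function(x, ...) {
  n <- length(x$null_pvalues)
  expected <- (seq_len(n) - 0.5) / n
  graphics::plot(expected, sort(x$null_pvalues),
                 xlab = "expected uniform quantile",
                 ylab = "observed null p-value",
                 main = "size-matched permutation null", ...)
  graphics::abline(0, 1, lty = 2)
  if (!is.null(x$observed_p)) graphics::abline(h = x$observed_p, col = 2)
  invisible(x)
}
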