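# Per-gene feature comparisons between two gene sets (pLI, mutation
# probability, haploinsufficiency, transcript length, selection metrics)
# and tissue-specificity enrichment against a reference panel.

#' Compare a per-gene feature between two gene sets
#'
#' Two-sided Wilcoxon rank-sum test plus pooled-SD Cohen's d on the raw
#' feature values (no transform). Genes missing the feature are dropped
#' with logged counts; genes in both sets are excluded from both groups.
#'
#' @param table Feature data.frame with a `gene` column
#'   (see [read_feature_table()]).
#' @param set_y,set_x Character vectors of gene identifiers.
#' @param feature Name of the feature column to compare.
#' @param set_names Length-2 labels for reporting.
#' @return A list of class `feature_comparison` with group sizes, medians,
#'   `p_wilcoxon` and Cohen's `d` (positive when `set_y` is higher).
#' @export
compare_feature <- function(table, set_y, set_x, feature,
                            set_names = c("Y", "X")) {
  if (!feature %in% names(table)) {
    stop(sprintf("feature `%s` absent from table; available: %s", feature,
                 paste(setdiff(names(table), "gene"), collapse = ", ")),
         call. = FALSE)
  }
  shared <- intersect(set_y, set_x)
  pick <- function(set, name) {
    v <- table[[feature]][table$gene %in% setdiff(set, shared)]
    dropped <- sum(is.na(v))
    if (dropped > 0L) {
      ess_log("dropped %d %s gene(s) missing `%s`", dropped, name, feature)
    }
    v <- v[!is.na(v)]
    if (length(v) < 2L) {
      stop(sprintf("set `%s` has %d gene(s) with `%s`; need >= 2",
                   name, length(v), feature), call. = FALSE)
    }
    v
  }
  y <- pick(set_y, set_names[[1]])
  x <- pick(set_x, set_names[[2]])
  wt <- wilcoxon_rank_sum(y, x)
  cd <- cohens_d_pooled(y, x)
  structure(
    list(feature = feature, set_names = set_names,
         n_y = length(y), n_x = length(x),
         median_y = stats::median(y), median_x = stats::median(x),
         W = wt$W, p_wilcoxon = wt$p, d = cd$d, sd_pooled = cd$sd_pooled),
    class = "feature_comparison"
  )
}

#' @export
print.feature_comparison <- function(x, ...) {
  cat(sprintf("feature comparison `%s`: %s (n=%d) vs %s (n=%d)\n",
              x$feature, x$set_names[[1]], x$n_y, x$set_names[[2]], x$n_x))
  cat(sprintf("  medians %.4g vs %.4g; Cohen's d = %.4f; Wilcoxon p = %.4g\n",
              x$median_y, x$median_x, x$d, x$p_wilcoxon))
  invisible(x)
}

#' Tissue-specificity enrichment of a gene set
#'
#' Fisher's exact enrichment of the query against a gene-to-tissue panel;
#' a thin wrapper over [set_enrichment()] with tissue categories.
#'
#' @param query Character vector of query genes.
#' @param panel Named list mapping tissue to member genes, or a data.frame
#'   with columns `gene`, `category` (or `gene`, `tissue`).
#' @param universe Background gene set.
#' @param ... Passed to [set_enrichment()].
#' @return An `enrichment_result`, one row per tissue.
#' @export
tissue_enrichment <- function(query, panel, universe, ...) {
  if (is.data.frame(panel) && "tissue" %in% names(panel)) {
    panel <- data.frame(gene = panel$gene, category = panel$tissue,
                        stringsAsFactors = FALSE)
  }
  set_enrichment(query, panel, universe, ...)
}
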