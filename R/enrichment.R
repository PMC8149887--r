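# Fisher's exact enrichment with Benjamini-Hochberg correction, and the
# Poisson expectation test for de novo mutation burden in a gene set.

#' Fisher's exact test on a 2x2 table
#'
#' One-sided `"greater"` is the upper hypergeometric tail of the top-left
#' cell (enrichment); `"two-sided"` sums the probabilities of all tables
#' with fixed margins whose probability does not exceed the observed
#' table's. The reported odds ratio is the sample odds ratio `ad / bc`
#' (`Inf` when a zero cell demands it), not a conditional MLE.
#'
#' @param counts 2x2 matrix or length-4 vector `(a, b, c, d)` read row-wise:
#'   `a` = in-set & in-category, `b` = in-set & out, `c` = out & in,
#'   `d` = out & out.
#' @param sidedness `"greater"` or `"two-sided"`.
#' @return A list with `odds_ratio` and `p`. A zero margin yields `p = 1`
#'   and an `NA` odds ratio.
#' @examples
#' fisher_exact(c(3, 1, 1, 3), "greater")$p  # 17/70
#' @export
fisher_exact <- function(counts, sidedness = c("greater", "two-sided")) {
  sidedness <- match.arg(sidedness)
  counts <- as.vector(t(as.matrix(counts)))
  if (length(counts) != 4L || any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("`counts` must be four non-negative integers", call. = FALSE)
  }
  a <- counts[[1]]; b <- counts[[2]]; cc <- counts[[3]]; d <- counts[[4]]
  n <- a + b + cc + d
  if (n == 0) stop("table total must be positive", call. = FALSE)
  row1 <- a + b
  col1 <- a + cc
  if (row1 == 0 || col1 == 0 || row1 == n || col1 == n) {
    return(list(odds_ratio = NA_real_, p = 1))
  }
  odds_ratio <- if (b * cc > 0) {
    (a * d) / (b * cc)
  } else if (a * d > 0) {
    Inf
  } else {
    NA_real_ # two zero cells on a diagonal: OR undefined
  }
  p <- if (sidedness == "greater") {
    stats::phyper(a - 1, col1, n - col1, row1, lower.tail = FALSE)
  } else {
    support <- max(0, row1 + col1 - n):min(row1, col1)
    probs <- stats::dhyper(support, col1, n - col1, row1)
    p_obs <- stats::dhyper(a, col1, n - col1, row1)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  list(odds_ratio = odds_ratio, p = min(1, p))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment, delegated to
#' [stats::p.adjust()]; order-preserving with the input.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Vector of q-values in the input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Enrichment of a gene set across categories
#'
#' One Fisher's exact test per category (module, risk list or tissue)
#' against a fixed gene universe, with BH correction across categories and a
#' significance flag at `alpha`. Query genes outside the universe are
#' dropped with a logged count.
#'
#' @param query Character vector of query genes.
#' @param categories Named list of category member vectors, or a data.frame
#'   with columns `gene`, `category`.
#' @param universe Character vector defining the background.
#' @param sidedness Passed to [fisher_exact()] (default `"greater"`).
#' @param alpha FDR threshold for the significance flag.
#' @return A data.frame of class `enrichment_result`: one row per category
#'   with the 2x2 counts, odds ratio, `p`, `q` and `significant`.
#' @export
set_enrichment <- function(query, categories, universe,
                           sidedness = c("greater", "two-sided"), alpha = 0.05) {
  sidedness <- match.arg(sidedness)
  alpha <- check_number(alpha, "alpha", min = 0, max = 1)
  universe <- as_gene_set(universe, warn_duplicates = FALSE)
  if (length(universe) == 0L) stop("universe must be non-empty", call. = FALSE)
  query <- as_gene_set(query, warn_duplicates = FALSE)
  outside <- sum(!query %in% universe)
  if (outside > 0L) {
    ess_log("dropped %d query gene(s) outside the universe", outside)
    query <- intersect(query, universe)
  }
  if (is.data.frame(categories)) {
    categories <- lapply(split(categories$gene, categories$category), unique)
  }
  if (is.null(names(categories)) || any(!nzchar(names(categories)))) {
    stop("categories must be named", call. = FALSE)
  }
  n_universe <- length(universe)
  n_query <- length(query)
  rows <- lapply(names(categories), function(nm) {
    members <- intersect(categories[[nm]], universe)
    a <- length(intersect(query, members))
    b <- n_query - a
    cc <- length(members) - a
    d <- n_universe - a - b - cc
    ft <- fisher_exact(c(a, b, cc, d), sidedness)
    data.frame(category = nm, in_set_in_cat = a, in_set_out = b,
               out_in_cat = cc, out_out = d,
               odds_ratio = ft$odds_ratio, p = ft$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < alpha
  class(out) <- c("enrichment_result", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "sidedness") <- sidedness
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment across %d categories (%s Fisher, FDR %.3g): %d significant\n",
              nrow(x), attr(x, "sidedness"), attr(x, "alpha"), sum(x$significant)))
  shown <- x[order(x$p), , drop = FALSE]
  print.data.frame(utils::head(shown, 10), row.names = FALSE, digits = 4)
  if (nrow(x) > 10) cat(sprintf("  ... and %d more\n", nrow(x) - 10))
  invisible(x)
}

#' Expected de novo mutation count in a gene set
#'
#' Under the standard de novo expectation model, the expected count for a
#' mutation class in a gene set is `lambda = 2 * n_trios * sum(p_g)` over
#' the set's per-gene per-generation mutation probabilities (two
#' transmissions per trio). Genes absent from the rate table are dropped
#' with a logged count.
#'
#' @param rates Data.frame with columns `gene`, `p_lof`,
#'   `p_protein_altering` (see [read_rate_table()]).
#' @param set Character vector of gene identifiers.
#' @param class `"lof"` or `"protein_altering"`.
#' @param n_trios Number of sequenced trios (> 0).
#' @return Expected count `lambda`.
#' @export
denovo_expected <- function(rates, set, class = c("lof", "protein_altering"),
                            n_trios) {
  class <- match.arg(class)
  n_trios <- check_number(n_trios, "n_trios")
  if (n_trios <= 0) stop("`n_trios` must be positive", call. = FALSE)
  set <- as_gene_set(set, warn_duplicates = FALSE)
  absent <- sum(!set %in% rates$gene)
  if (absent > 0L) {
    ess_log("%d set gene(s) absent from the rate table were dropped", absent)
  }
  col <- if (class == "lof") "p_lof" else "p_protein_altering"
  2 * n_trios * sum(rates[[col]][rates$gene %in% set])
}

#' Poisson upper-tail test for de novo mutation burden
#'
#' `p = P(X >= observed | lambda)` for `X ~ Poisson(lambda)`; an observed
#' count of 0 gives p = 1.
#'
#' @param observed Non-negative integer count of de novo mutations in the
#'   set.
#' @param lambda Expected count from [denovo_expected()].
#' @return Upper-tail p-value.
#' @examples
#' denovo_test(2, 0.2)  # 1 - exp(-0.2) * 1.2
#' @export
denovo_test <- function(observed, lambda) {
  observed <- check_count(observed, "observed")
  lambda <- check_number(lambda, "lambda", min = 0)
  if (observed == 0L) return(1)
  stats::ppois(observed - 1, lambda, lower.tail = FALSE)
}

#' De novo burden test for a gene set, both mutation classes
#'
#' Convenience wrapper combining [denovo_expected()] and [denovo_test()]
#' for a `denovo_model` (as produced by [gen_denovo()]) or explicit pieces.
#'
#' @param model A list with `rates`, `set`, `n_trios` and `observed` (named
#'   per class).
#' @return Data.frame with one row per class: `class`, `lambda`, `observed`,
#'   `p`.
#' @export
denovo_burden <- function(model) {
  classes <- c("lof", "protein_altering")
  rows <- lapply(classes, function(cl) {
    lambda <- denovo_expected(model$rates, model$set, cl, model$n_trios)
    data.frame(class = cl, lambda = lambda,
               observed = as.integer(model$observed[[cl]]),
               p = denovo_test(model$observed[[cl]], lambda),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
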