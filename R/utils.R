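# Internal helpers shared across the package. No science here.

`%||%` <- function(a, b) if (is.null(a)) b else a

ess_log <- function(fmt, ...) {
  message("[esscomp] ", sprintf(fmt, ...))
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single non-missing number", name), call. = FALSE)
  }
  if (x < min || x > max) {
    stop(sprintf("`%s` must be in [%s, %s], got %s", name, min, max, x), call. = FALSE)
  }
  as.numeric(x)
}

check_count <- function(x, name, min = 0L) {
  x <- check_number(x, name, min = min)
  if (x != round(x)) {
    stop(sprintf("`%s` must be a whole number, got %s", name, x), call. = FALSE)
  }
  as.integer(x)
}

#' Normalise a character vector into a gene set
#'
#' Trims whitespace, drops empty strings and removes duplicates while
#' preserving first-occurrence order. Matching everywhere in the package is
#' exact and case-sensitive; no symbol-alias resolution is attempted.
#'
#' @param x Character vector of gene identifiers.
#' @param warn_duplicates Log a message when duplicates are collapsed.
#' @return Character vector with unique, trimmed identifiers.
#' @export
as_gene_set <- function(x, warn_duplicates = TRUE) {
  if (!is.character(x)) stop("gene identifiers must be character", call. = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x)]
  dup <- duplicated(x)
  if (any(dup) && warn_duplicates) {
    ess_log("dropped %d duplicated gene identifier(s)", sum(dup))
  }
  x[!dup]
}

#' Adjusted Rand index between two labelings
#'
#' Used to score recovery of planted module memberships by the synthetic
#' benchmark. Standard Hubert-Arabie formulation; two identical one-cluster
#' labelings score 1.
#'
#' @param a,b Two label vectors of equal length (any atomic type).
#' @return A number in [-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length", call. = FALSE)
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
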