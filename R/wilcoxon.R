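# Two-sided Wilcoxon rank-sum test with an exact small-sample branch.
#
# The exact branch (no ties, n_x + n_y <= exact_limit) defines the two-sided
# p as min(1, 2 * min(lower tail, upper tail)) with both tails inclusive of
# the observed statistic, which is identical to exhaustive enumeration over
# all rank assignments. Larger or tied samples use the normal approximation
# with tie correction and a continuity correction.

#' Two-sided Wilcoxon rank-sum test
#'
#' @param x,y Numeric score vectors, each of length >= 1.
#' @param exact_limit Exact enumeration is used when `length(x) + length(y)`
#'   is at most this and there are no ties.
#' @return A list with `W` (rank sum of `x` in the pooled sample), `U`
#'   (Mann-Whitney statistic of `x`), `p` (two-sided), and `method`
#'   (`"exact"` or `"normal"`).
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))$p  # 1/3
#' @export
wilcoxon_rank_sum <- function(x, y, exact_limit = 20L) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) {
    stop("both samples must contain at least one value", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("scores must not contain NA", call. = FALSE)
  nx <- length(x)
  ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(nx)])
  U <- W - nx * (nx + 1) / 2
  ties <- length(unique(pooled)) < length(pooled)

  if (!ties && nx + ny <= exact_limit) {
    lower <- stats::pwilcox(U, nx, ny)
    upper <- stats::pwilcox(U - 1, nx, ny, lower.tail = FALSE)
    p <- min(1, 2 * min(lower, upper))
    return(list(W = W, U = U, p = p, method = "exact"))
  }

  n <- nx + ny
  tie_counts <- table(pooled)
  sigma2 <- (nx * ny / 12) *
    ((n + 1) - sum(tie_counts^3 - tie_counts) / (n * (n - 1)))
  if (sigma2 <= 0) {
    warning("all values identical across both samples; p = 1", call. = FALSE)
    return(list(W = W, U = U, p = 1, method = "normal"))
  }
  z <- U - nx * ny / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2) # continuity correction toward the mean
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(W = W, U = U, p = p, method = "normal")
}

#' Pooled-standard-deviation Cohen's d
#'
#' Standardized mean difference `d = (mean(y) - mean(x)) / s` where `s` is
#' the pooled sample standard deviation
#' `sqrt(((n_x - 1) s_x^2 + (n_y - 1) s_y^2) / (n_x + n_y - 2))`. The pooled
#' form is used because the two groups generally have unequal sizes.
#'
#' @param y,x Numeric vectors, each of length >= 2. `y` is the first group,
#'   so positive `d` means `y` sits higher than `x`.
#' @return A list with `n_y`, `n_x`, `mean_y`, `mean_x`, `sd_y`, `sd_x`,
#'   `sd_pooled`, `d`. When the pooled SD is zero `d` is `NA` with a warning.
#' @examples
#' cohens_d_pooled(c(3, 5), c(0, 2))$d  # 3 / sqrt(2)
#' @export
cohens_d_pooled <- function(y, x) {
  y <- as.numeric(y)
  x <- as.numeric(x)
  if (length(y) < 2L || length(x) < 2L) {
    stop("both groups need at least two values for a pooled SD", call. = FALSE)
  }
  ny <- length(y)
  nx <- length(x)
  sy <- stats::sd(y)
  sx <- stats::sd(x)
  s <- sqrt(((nx - 1) * sx^2 + (ny - 1) * sy^2) / (nx + ny - 2))
  d <- if (s > 0) {
    (mean(y) - mean(x)) / s
  } else {
    warning("pooled standard deviation is zero; Cohen's d undefined", call. = FALSE)
    NA_real_
  }
  list(n_y = ny, n_x = nx, mean_y = mean(y), mean_x = mean(x),
       sd_y = sy, sd_x = sx, sd_pooled = s, d = d)
}
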