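# Independent brute-force oracles used to validate the analytic routines.
# These deliberately share no code with the implementations they check.

# Two-sided Wilcoxon rank-sum p by exhaustive enumeration over all
# assignments of the pooled ranks to the first sample; both tails inclusive
# of the observed rank sum.
enum_wilcoxon_p <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  assignments <- utils::combn(length(r), nx)
  ws <- apply(assignments, 2, function(i) sum(r[i]))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# Fisher p by direct enumeration of all 2x2 tables with the observed
# margins, using table probabilities computed from binomial coefficients.
enum_fisher_p <- function(a, b, cc, d, sidedness) {
  n <- a + b + cc + d
  row1 <- a + b
  col1 <- a + cc
  support <- max(0, row1 + col1 - n):min(row1, col1)
  prob_of <- function(k) {
    choose(row1, k) * choose(n - row1, col1 - k) / choose(n, col1)
  }
  probs <- vapply(support, prob_of, numeric(1))
  if (sidedness == "greater") {
    sum(probs[support >= a])
  } else {
    sum(probs[probs <= prob_of(a) * (1 + 1e-7)])
  }
}

# Naive O(n^3) topological overlap straight from the formula.
naive_tom <- function(a) {
  n <- nrow(a)
  out <- matrix(0, n, n)
  k <- numeric(n)
  for (i in seq_len(n)) k[i] <- sum(a[i, -i])
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) {
        out[i, j] <- 1
      } else {
        l <- 0
        for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
        out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
      }
    }
  }
  out
}

random_symmetric_adjacency <- function(n) {
  m <- matrix(stats::runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

random_2x2 <- function(max_total = 40) {
  repeat {
    counts <- stats::rmultinom(1, sample.int(max_total, 1), rep(1 / 4, 4))[, 1]
    # margins must all be positive for a non-degenerate table
    if (all(c(counts[1] + counts[2], counts[3] + counts[4],
              counts[1] + counts[3], counts[2] + counts[4]) > 0)) {
      return(counts)
    }
  }
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
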