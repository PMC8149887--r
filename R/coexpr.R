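# Simplified signed weighted co-expression network analysis on a
# developmental expression matrix: soft-thresholded signed adjacency,
# topological overlap, average-linkage module detection with a static cut,
# module eigengenes, eigengene-correlation merging and temporal-pattern
# classification of the module trajectories.

get_values <- function(expr) {
  if (inherits(expr, "expression_matrix")) expr$values else as.matrix(expr)
}

# Biweight midcorrelation between rows of m; tuning constant fixed at 9
# median absolute deviations. Rows with zero MAD fall back to the
# mean/SD-standardized (Pearson) row.
bicor_rows <- function(m) {
  med <- apply(m, 1, stats::median)
  madv <- apply(m, 1, stats::mad, constant = 1)
  centred <- sweep(m, 1, med)
  u <- sweep(centred, 1, pmax(9 * madv, .Machine$double.eps), "/")
  w <- (1 - u^2)^2 * (abs(u) < 1)
  xt <- centred * w
  degenerate <- madv == 0
  if (any(degenerate)) {
    mu <- rowMeans(m[degenerate, , drop = FALSE])
    xt[degenerate, ] <- sweep(m[degenerate, , drop = FALSE], 1, mu)
  }
  norms <- sqrt(rowSums(xt^2))
  xt <- sweep(xt, 1, pmax(norms, .Machine$double.eps), "/")
  out <- tcrossprod(xt)
  diag(out) <- 1
  pmin(pmax(out, -1), 1)
}

#' Signed soft-thresholded co-expression adjacency
#'
#' `a_ij = ((1 + cor_ij) / 2)^beta`, so perfectly anti-correlated genes get
#' adjacency 0 and perfectly correlated genes 1 (a *signed* network).
#' Correlation is Pearson by default with biweight midcorrelation as a
#' robust option. Zero-variance genes are removed with a logged count.
#'
#' @param expr An [expression_matrix()] or a genes x samples numeric matrix.
#' @param beta Positive soft-thresholding power (default 15).
#' @param method `"pearson"` or `"biweight"`.
#' @return Symmetric gene x gene adjacency matrix in [0, 1] with unit
#'   diagonal.
#' @export
signed_adjacency <- function(expr, beta = 15, method = c("pearson", "biweight")) {
  method <- match.arg(method)
  beta <- check_number(beta, "beta", min = .Machine$double.eps)
  m <- get_values(expr)
  if (ncol(m) < 2L) stop("need at least two samples", call. = FALSE)
  v <- apply(m, 1, stats::var)
  if (any(v == 0)) {
    ess_log("removed %d zero-variance gene(s) before network construction", sum(v == 0))
    m <- m[v > 0, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("need at least two genes with variance", call. = FALSE)
  cors <- if (method == "pearson") stats::cor(t(m)) else bicor_rows(m)
  a <- ((1 + cors) / 2)^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' Neighborhood-sharing similarity of a weighted network:
#' `tom_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over `u != i, j` and `k_i` the connectivity
#' `sum_u a_iu` over `u != i`; the diagonal is set to 1.
#'
#' @param adjacency Symmetric matrix with entries in [0, 1].
#' @return Symmetric TOM matrix in [0, 1].
#' @export
topological_overlap <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (nrow(a) != ncol(a) || max(abs(a - t(a))) > 1e-8) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  if (min(a) < -1e-12 || max(a) > 1 + 1e-12) {
    stop("adjacency entries must lie in [0, 1]", call. = FALSE)
  }
  a0 <- a
  diag(a0) <- 0
  l <- a0 %*% a0
  k <- rowSums(a0)
  denom <- outer(k, k, pmin) + 1 - a0
  tom <- (l + a0) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity
#' (1 - TOM) with a static cut at `cut_height`. Clusters smaller than
#' `min_module_size` are assigned the reserved unassigned label 0; retained
#' modules are renumbered 1, 2, ... by decreasing size.
#'
#' @param tom Topological overlap matrix.
#' @param min_module_size Smallest retained module (default 30).
#' @param cut_height Static dendrogram cut height on the 1 - TOM scale.
#' @return An object of class `module_assignment`: a named integer vector
#'   (gene -> module label, 0 = unassigned) with a `sizes` attribute.
#' @export
detect_modules <- function(tom, min_module_size = 30L, cut_height = 0.75) {
  min_module_size <- check_count(min_module_size, "min_module_size", min = 1L)
  cut_height <- check_number(cut_height, "cut_height", min = 0)
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  raw <- stats::cutree(hc, h = cut_height)
  new_module_assignment(raw, min_module_size,
                        genes = rownames(tom) %||% names(raw))
}

# Relabel raw cluster ids: drop clusters below the size threshold to label
# 0 and renumber the rest by decreasing size (ties broken by original id).
# A raw id of 0 is already "unassigned" and stays reserved.
new_module_assignment <- function(raw, min_module_size, genes = names(raw)) {
  sizes <- table(raw[raw != 0])
  keep_ids <- names(sizes)[sizes >= min_module_size]
  labels <- integer(length(raw))
  if (length(keep_ids)) {
    ord <- keep_ids[order(-sizes[keep_ids], as.integer(keep_ids))]
    for (j in seq_along(ord)) labels[raw == as.integer(ord[[j]])] <- j
  } else {
    warning("no cluster reached the minimum module size; all genes unassigned",
            call. = FALSE)
  }
  names(labels) <- genes
  structure(labels, sizes = table(labels[labels > 0]), class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  sizes <- attr(x, "sizes")
  cat(sprintf("module assignment: %d gene(s), %d module(s), %d unassigned\n",
              length(x), length(sizes), sum(unclass(x) == 0)))
  if (length(sizes)) {
    cat("  sizes:", paste(sprintf("M%s=%s", names(sizes), sizes), collapse = " "), "\n")
  }
  invisible(x)
}

#' Module eigengene
#'
#' First principal component of the module's gene-standardized submatrix.
#' The per-sample score vector has unit norm and its sign is oriented so
#' that its correlation with the module's mean standardized expression is
#' non-negative, which makes temporal patterns well-defined.
#'
#' @param expr [expression_matrix()] or genes x samples matrix.
#' @param assignment A `module_assignment` (or named integer vector).
#' @param module Module label to summarize.
#' @return An object of class `eigengene` with `module`, `scores` (one per
#'   sample, unit norm) and `var_explained`.
#' @export
module_eigengene <- function(expr, assignment, module) {
  m <- get_values(expr)
  genes <- names(assignment)[unclass(assignment) == module]
  genes <- intersect(genes, rownames(m))
  if (length(genes) < 2L) {
    stop(sprintf("module %s has %d usable gene(s); need >= 2", module, length(genes)),
         call. = FALSE)
  }
  sub <- m[genes, , drop = FALSE]
  v <- apply(sub, 1, stats::var)
  if (any(v == 0)) {
    sub <- sub[v > 0, , drop = FALSE]
    if (nrow(sub) < 2L) stop("module is degenerate after removing constant genes",
                             call. = FALSE)
  }
  z <- t(scale(t(sub))) # gene rows to zero mean, unit variance
  sv <- svd(z)
  if (sv$d[[1]] <= sqrt(.Machine$double.eps)) {
    stop("degenerate (rank-0) module submatrix", call. = FALSE)
  }
  scores <- sv$v[, 1]
  profile <- colMeans(z)
  orient <- if (stats::sd(profile) > 0) stats::cor(scores, profile) else sum(sv$u[, 1])
  if (!is.na(orient) && orient < 0) scores <- -scores
  structure(
    list(module = module, scores = scores,
         var_explained = sv$d[[1]]^2 / sum(sv$d^2)),
    class = "eigengene"
  )
}

#' Merge modules with highly correlated eigengenes
#'
#' Iteratively merges the module pair with the highest eigengene correlation
#' above `merge_threshold`, recomputes the merged eigengene, and repeats to
#' a fixpoint. Ties are broken deterministically in favour of the pair with
#' the smaller first label; merged modules keep the smaller label, and the
#' result is renumbered by decreasing size.
#'
#' @param expr [expression_matrix()] or genes x samples matrix.
#' @param assignment A `module_assignment`.
#' @param merge_threshold Eigengene correlation above which modules merge
#'   (default 0.9).
#' @return An updated `module_assignment`.
#' @export
merge_modules <- function(expr, assignment, merge_threshold = 0.9) {
  merge_threshold <- check_number(merge_threshold, "merge_threshold",
                                  min = 1e-12, max = 1)
  labels <- unclass(assignment)
  attributes(labels) <- list(names = names(assignment))
  repeat {
    ids <- sort(unique(labels[labels > 0]))
    if (length(ids) < 2L) break
    eg <- vapply(ids, function(id) {
      tmp <- structure(labels, class = "module_assignment")
      module_eigengene(expr, tmp, id)$scores
    }, numeric(ncol(get_values(expr))))
    cors <- stats::cor(eg)
    diag(cors) <- -Inf
    best <- max(cors)
    if (best <= merge_threshold) break
    pair <- which(cors == best, arr.ind = TRUE)
    pair <- pair[order(pmin(pair[, 1], pair[, 2]), pmax(pair[, 1], pair[, 2])), ,
                 drop = FALSE][1, ]
    from <- ids[max(pair)]
    to <- ids[min(pair)]
    labels[labels == from] <- to
  }
  new_module_assignment(labels, min_module_size = 1L, genes = names(labels))
}

#' Classify a module eigengene's temporal pattern
#'
#' Summarizes the (standardized) eigengene trajectory by its mean in three
#' windows -- the first prenatal third, the last prenatal third (sample-count
#' thirds of the age-ordered prenatal samples) and the postnatal period --
#' and assigns one of three developmental patterns with decision margin
#' `margin` (in SD units): rising before birth then sustained
#' (`prenatal_rise_sustained`), flat-low before birth then intermediate
#' (`low_prenatal_mid`), or high early then dropping before birth
#' (`prenatal_high_drop`); anything else is `unclassified`.
#'
#' @param scores Numeric eigengene scores, one per sample.
#' @param age_pcd Sample ages in post-conception days.
#' @param prenatal Logical prenatal flags; at least 3 prenatal and 3
#'   postnatal samples are required.
#' @param margin Decision margin in standard deviations (default 0.25).
#' @return A list of class `temporal_pattern` with `pattern` and the three
#'   window means `early`, `late`, `postnatal`.
#' @export
classify_temporal_pattern <- function(scores, age_pcd, prenatal, margin = 0.25) {
  margin <- check_number(margin, "margin", min = 0)
  prenatal <- as.logical(prenatal)
  if (sum(prenatal) < 3L || sum(!prenatal) < 3L) {
    stop(sprintf("need >= 3 prenatal and >= 3 postnatal samples; have %d and %d",
                 sum(prenatal), sum(!prenatal)), call. = FALSE)
  }
  z <- (scores - mean(scores)) / stats::sd(scores)
  pre <- z[prenatal][order(age_pcd[prenatal])]
  n_pre <- length(pre)
  k <- max(1L, floor(n_pre / 3))
  early <- mean(pre[seq_len(k)])
  late <- mean(pre[seq.int(n_pre - k + 1L, n_pre)])
  post <- mean(z[!prenatal])
  d_pre <- late - early
  d_post <- post - late
  pattern <- if (d_pre > margin && d_post >= -margin) {
    "prenatal_rise_sustained"
  } else if (d_pre < -margin && d_post <= margin) {
    "prenatal_high_drop"
  } else if (abs(d_pre) <= margin && d_post > margin) {
    "low_prenatal_mid"
  } else {
    "unclassified"
  }
  structure(list(pattern = pattern, early = early, late = late, postnatal = post),
            class = "temporal_pattern")
}

#' @export
print.temporal_pattern <- function(x, ...) {
  cat(sprintf("temporal pattern: %s (early %.2f, late %.2f, postnatal %.2f)\n",
              x$pattern, x$early, x$late, x$postnatal))
  invisible(x)
}

#' Full co-expression module pipeline
#'
#' Composes [signed_adjacency()], [topological_overlap()],
#' [detect_modules()], [module_eigengene()], [merge_modules()] and
#' [classify_temporal_pattern()] into one call.
#'
#' @param expr An [expression_matrix()].
#' @param beta,method,min_module_size,cut_height,merge_threshold,margin See
#'   the individual steps.
#' @param classify Classify temporal patterns (needs >= 3 prenatal and >= 3
#'   postnatal samples).
#' @return An object of class `coexpr_fit` with `assignment`, `eigengenes`
#'   (module x sample matrix), `var_explained`, `patterns` (data.frame) and
#'   the parameters used.
#' @export
run_coexpression <- function(expr, beta = 15, method = c("pearson", "biweight"),
                             min_module_size = 30L, cut_height = 0.75,
                             merge_threshold = 0.9, margin = 0.25,
                             classify = TRUE) {
  stopifnot(inherits(expr, "expression_matrix"))
  method <- match.arg(method)
  adj <- signed_adjacency(expr, beta = beta, method = method)
  tom <- topological_overlap(adj)
  assignment <- detect_modules(tom, min_module_size = min_module_size,
                               cut_height = cut_height)
  ids <- sort(unique(unclass(assignment)[unclass(assignment) > 0]))
  if (length(ids) > 1L) {
    assignment <- merge_modules(expr, assignment, merge_threshold = merge_threshold)
    ids <- sort(unique(unclass(assignment)[unclass(assignment) > 0]))
  }
  n_samp <- ncol(expr$values)
  eigengenes <- matrix(numeric(0), nrow = 0, ncol = n_samp,
                       dimnames = list(NULL, colnames(expr$values)))
  var_explained <- numeric(0)
  patterns <- NULL
  if (length(ids)) {
    eg <- lapply(ids, function(id) module_eigengene(expr, assignment, id))
    eigengenes <- do.call(rbind, lapply(eg, `[[`, "scores"))
    dimnames(eigengenes) <- list(paste0("M", ids), colnames(expr$values))
    var_explained <- stats::setNames(vapply(eg, `[[`, numeric(1), "var_explained"),
                                     rownames(eigengenes))
    if (classify) {
      pat <- lapply(eg, function(e) {
        classify_temporal_pattern(e$scores, expr$age_pcd, expr$prenatal,
                                  margin = margin)
      })
      patterns <- data.frame(
        module = rownames(eigengenes),
        pattern = vapply(pat, `[[`, character(1), "pattern"),
        early = vapply(pat, `[[`, numeric(1), "early"),
        late = vapply(pat, `[[`, numeric(1), "late"),
        postnatal = vapply(pat, `[[`, numeric(1), "postnatal"),
        stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(assignment = assignment, eigengenes = eigengenes,
         var_explained = var_explained, patterns = patterns,
         age_pcd = expr$age_pcd, prenatal = expr$prenatal,
         params = list(beta = beta, method = method,
                       min_module_size = min_module_size,
                       cut_height = cut_height,
                       merge_threshold = merge_threshold, margin = margin)),
    class = "coexpr_fit"
  )
}

#' @export
print.coexpr_fit <- function(x, ...) {
  print(x$assignment)
  if (!is.null(x$patterns)) {
    cat("temporal patterns:\n")
    for (i in seq_len(nrow(x$patterns))) {
      cat(sprintf("  %s: %s\n", x$patterns$module[[i]], x$patterns$pattern[[i]]))
    }
  }
  invisible(x)
}

#' Plot module eigengene trajectories across development
#'
#' @param x A `coexpr_fit`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.coexpr_fit <- function(x, ...) {
  if (nrow(x$eigengenes) == 0L) {
    stop("no modules to plot", call. = FALSE)
  }
  graphics::matplot(log10(x$age_pcd), t(x$eigengenes), type = "l", lty = 1,
                    xlab = "log10 age (post-conception days)",
                    ylab = "eigengene score", ...)
  graphics::abline(v = log10(266), lty = 2) # birth
  graphics::legend("topright", legend = rownames(x$eigengenes),
                   col = seq_len(nrow(x$eigengenes)), lty = 1, cex = 0.7)
  invisible(x)
}
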