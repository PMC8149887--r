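# Ortholog mapping and the three-way partition of two essential-gene sets.

#' Map a gene set through an ortholog table
#'
#' Translates (for example) mouse screen hits into human symbols. Every
#' target of every mapped source is kept, so one-to-many orthology expands
#' the set and many-to-one collapses by union; unmapped sources are counted
#' and logged, never errors.
#'
#' @param source_set Character vector of source-species identifiers.
#' @param map Data.frame with columns `source`, `target`
#'   (see [read_ortholog_map()]).
#' @return Character vector of unique target identifiers.
#' @export
map_orthologs <- function(source_set, map) {
  if (!is.data.frame(map) || !all(c("source", "target") %in% names(map)) ||
      nrow(map) == 0L) {
    stop("`map` must be a non-empty data.frame with columns `source`, `target`",
         call. = FALSE)
  }
  source_set <- as_gene_set(source_set, warn_duplicates = FALSE)
  hit <- map$source %in% source_set
  unmapped <- sum(!source_set %in% map$source)
  if (unmapped > 0L) {
    ess_log("%d source gene(s) had no ortholog and were dropped", unmapped)
  }
  targets <- unique(map$target[hit])
  if (length(targets) == 0L) {
    warning("ortholog mapping produced an empty gene set", call. = FALSE)
  }
  targets
}

#' Partition two gene sets into specific and shared blocks
#'
#' Exact set algebra on (already ortholog-mapped) identifiers:
#' `a_specific = A \ B`, `b_specific = B \ A`, `shared = A` \eqn{\cap} `B`.
#' With the two published screen lists (3838 neuronal essential human genes,
#' 2149 common essential genes, 698 in common) this yields the 3140
#' neuronal-specific and 1451 cell-line-specific blocks.
#'
#' @param set_a,set_b Non-empty character vectors.
#' @param names Length-2 labels for the two sets, used in printing.
#' @return An object of class `gene_partition` with elements `a_specific`,
#'   `b_specific`, `shared` and `set_names`.
#' @examples
#' p <- partition_sets(c("x", "y", "z"), c("y", "w"))
#' lengths(p[c("a_specific", "b_specific", "shared")])
#' @export
partition_sets <- function(set_a, set_b, names = c("A", "B")) {
  set_a <- as_gene_set(set_a, warn_duplicates = FALSE)
  set_b <- as_gene_set(set_b, warn_duplicates = FALSE)
  if (length(set_a) == 0L || length(set_b) == 0L) {
    stop("both input sets must be non-empty", call. = FALSE)
  }
  structure(
    list(a_specific = setdiff(set_a, set_b),
         b_specific = setdiff(set_b, set_a),
         shared = intersect(set_a, set_b),
         set_names = as.character(names)),
    class = "gene_partition"
  )
}

#' @export
print.gene_partition <- function(x, ...) {
  cat("gene set partition\n")
  cat(sprintf("  %s-specific: %d\n", x$set_names[[1]], length(x$a_specific)))
  cat(sprintf("  %s-specific: %d\n", x$set_names[[2]], length(x$b_specific)))
  cat(sprintf("  shared:      %d\n", length(x$shared)))
  invisible(x)
}

#' @export
summary.gene_partition <- function(object, ...) {
  data.frame(
    set_a = object$set_names[[1]],
    set_b = object$set_names[[2]],
    n_a = length(object$a_specific) + length(object$shared),
    n_b = length(object$b_specific) + length(object$shared),
    a_specific = length(object$a_specific),
    b_specific = length(object$b_specific),
    shared = length(object$shared),
    stringsAsFactors = FALSE
  )
}
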