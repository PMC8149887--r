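# Readers and writers for the plain-text formats the pipeline consumes:
# gene lists (one symbol per line), GMT collections, DE result tables,
# expression matrices with sample metadata, ortholog maps, feature tables,
# category maps and mutation-rate tables. All output is TSV with a header,
# floats written at 6 significant digits.

#' Read gene sets from a list file or a GMT file
#'
#' A list file holds one identifier per line; a GMT file holds one set per
#' line with at least three tab-separated fields (name, description,
#' members...). Identifiers are whitespace-trimmed, case is preserved and
#' duplicates are dropped with a logged count.
#'
#' @param path Input file.
#' @param format `"list"` (default) or `"gmt"`.
#' @return For `"list"`, a character vector; for `"gmt"`, a named list of
#'   character vectors in file order.
#' @export
read_gene_set <- function(path, format = c("list", "gmt")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) stop("empty gene set file: ", path, call. = FALSE)
  if (format == "list") {
    return(as_gene_set(lines))
  }
  sets <- list()
  for (i in which(keep)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("malformed GMT row at line %d of %s: expected >= 3 tab-separated fields",
                   i, path), call. = FALSE)
    }
    sets[[trimws(fields[[1]])]] <- as_gene_set(fields[-(1:2)])
  }
  sets
}

#' Write a gene set as a one-symbol-per-line list file
#'
#' @param genes Character vector of identifiers.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(as_gene_set(genes, warn_duplicates = FALSE), path)
  invisible(path)
}

# Column-name synonym tables for DE results produced by standard DE tools.
.de_synonyms <- list(
  gene   = c("gene", "gene_id", "geneid", "symbol", "id", "gene_symbol"),
  log2fc = c("log2fc", "log2foldchange", "lfc", "logfc", "log2_fold_change"),
  pvalue = c("pvalue", "p", "pval", "p_value"),
  padj   = c("padj", "adj_p", "p_adj", "p_adjusted", "fdr", "qvalue", "adj_pvalue")
)

match_column <- function(found, synonyms) {
  norm <- tolower(gsub("[^[:alnum:]]", "", found))
  hit <- which(norm %in% gsub("[^[:alnum:]]", "", synonyms))
  if (length(hit)) hit[[1]] else NA_integer_
}

#' Read a per-gene differential-expression result table
#'
#' Consumes the output schema of standard DE tools: per gene a log2 fold
#' change, a raw p-value and an adjusted p-value. Column names are matched
#' case-insensitively against configurable synonym lists. Rows missing the
#' selected p-value are dropped with a logged count; duplicated gene
#' identifiers keep the first occurrence.
#'
#' @param path TSV file with a header.
#' @param p_column Which p-value column drives the missing-data rule:
#'   `"raw"` or `"adjusted"`.
#' @param synonyms Named list overriding the default column synonyms; names
#'   among `gene`, `log2fc`, `pvalue`, `padj`.
#' @return A data.frame with columns `gene`, `log2fc`, `pvalue`, `padj`.
#' @export
read_de_table <- function(path, p_column = c("raw", "adjusted"), synonyms = list()) {
  p_column <- match.arg(p_column)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  syn <- utils::modifyList(.de_synonyms, synonyms)
  idx <- vapply(names(syn), function(f) match_column(names(raw), syn[[f]]), integer(1))
  if (anyNA(idx)) {
    stop(sprintf("missing required column(s) %s; found: %s",
                 paste(names(syn)[is.na(idx)], collapse = ", "),
                 paste(names(raw), collapse = ", ")), call. = FALSE)
  }
  de <- data.frame(
    gene = trimws(as.character(raw[[idx[["gene"]]]])),
    log2fc = as.numeric(raw[[idx[["log2fc"]]]]),
    pvalue = as.numeric(raw[[idx[["pvalue"]]]]),
    padj = as.numeric(raw[[idx[["padj"]]]]),
    stringsAsFactors = FALSE
  )
  sel <- if (p_column == "raw") de$pvalue else de$padj
  missing_p <- is.na(sel)
  if (any(missing_p)) {
    ess_log("dropped %d row(s) with missing %s p-value", sum(missing_p), p_column)
    de <- de[!missing_p, , drop = FALSE]
  }
  dup <- duplicated(de$gene)
  if (any(dup)) {
    ess_log("dropped %d duplicated gene id(s), keeping first occurrence", sum(dup))
    de <- de[!dup, , drop = FALSE]
  }
  bad <- c(de$pvalue[!is.na(de$pvalue)], de$padj[!is.na(de$padj)])
  if (length(bad) && (min(bad) < 0 || max(bad) > 1)) {
    stop("p-values outside [0, 1] in ", path, call. = FALSE)
  }
  rownames(de) <- NULL
  de
}

#' Construct a developmental expression matrix
#'
#' Wraps a genes x samples matrix with per-sample age (post-conception days)
#' and a prenatal flag. Samples are reordered by ascending age; genes with
#' zero variance are flagged but retained.
#'
#' @param values Numeric matrix, genes in rows, samples in columns
#'   (dimnames required).
#' @param age_pcd Numeric vector of sample ages in post-conception days.
#' @param prenatal Logical vector, `TRUE` for prenatal samples.
#' @return An object of class `expression_matrix` with elements `values`,
#'   `age_pcd`, `prenatal`, `zero_variance`.
#' @export
expression_matrix <- function(values, age_pcd, prenatal) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene rownames and sample colnames", call. = FALSE)
  }
  if (anyNA(values)) stop("expression values must not contain NA", call. = FALSE)
  if (length(age_pcd) != ncol(values) || length(prenatal) != ncol(values)) {
    stop("`age_pcd` and `prenatal` must have one entry per sample", call. = FALSE)
  }
  ord <- order(age_pcd)
  values <- values[, ord, drop = FALSE]
  v <- apply(values, 1, stats::var)
  structure(
    list(values = values,
         age_pcd = as.numeric(age_pcd)[ord],
         prenatal = as.logical(prenatal)[ord],
         zero_variance = v == 0),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  age range %.0f-%.0f pcd; %d prenatal, %d postnatal\n",
              min(x$age_pcd), max(x$age_pcd), sum(x$prenatal), sum(!x$prenatal)))
  if (any(x$zero_variance)) {
    cat(sprintf("  %d zero-variance gene(s) flagged\n", sum(x$zero_variance)))
  }
  invisible(x)
}

#' Read an expression matrix and its sample metadata
#'
#' The matrix TSV has genes in rows (first column holds gene identifiers)
#' and one column per sample; the metadata TSV has columns `sample`,
#' `age_pcd` and `prenatal`, one row per matrix column.
#'
#' @param matrix_path,metadata_path TSV files.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(matrix_path, metadata_path) {
  for (p in c(matrix_path, metadata_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  raw <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  values <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- trimws(as.character(raw[[1]]))
  meta <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample", "age_pcd", "prenatal")
  if (!all(need %in% names(meta))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  only_matrix <- setdiff(colnames(values), meta$sample)
  only_meta <- setdiff(meta$sample, colnames(values))
  if (length(only_matrix) || length(only_meta)) {
    stop(sprintf("sample mismatch between matrix and metadata; matrix-only: {%s}; metadata-only: {%s}",
                 paste(only_matrix, collapse = ", "),
                 paste(only_meta, collapse = ", ")), call. = FALSE)
  }
  meta <- meta[match(colnames(values), meta$sample), , drop = FALSE]
  prenatal <- meta$prenatal
  if (!is.logical(prenatal)) prenatal <- as.logical(as.integer(prenatal))
  em <- expression_matrix(values, meta$age_pcd, prenatal)
  if (any(em$zero_variance)) {
    ess_log("flagged %d zero-variance gene(s)", sum(em$zero_variance))
  }
  em
}

#' Write an expression matrix and metadata back to TSV
#'
#' Round-trip companion of [read_expression()].
#'
#' @param expr An `expression_matrix`.
#' @param matrix_path,metadata_path Destination files.
#' @return Invisibly, the two paths.
#' @export
write_expression <- function(expr, matrix_path, metadata_path) {
  stopifnot(inherits(expr, "expression_matrix"))
  df <- data.frame(gene = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, matrix_path)
  meta <- data.frame(sample = colnames(expr$values),
                     age_pcd = expr$age_pcd,
                     prenatal = expr$prenatal,
                     stringsAsFactors = FALSE)
  write_tsv(meta, metadata_path)
  invisible(c(matrix_path, metadata_path))
}

#' Read a mouse-to-human ortholog map
#'
#' @param path TSV with columns `source` and `target`; duplicate pairs are
#'   collapsed. One source may map to several targets and vice versa.
#' @return A data.frame with columns `source`, `target`.
#' @export
read_ortholog_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  map <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("source", "target") %in% names(map))) {
    stop("ortholog map must have columns `source` and `target`; found: ",
         paste(names(map), collapse = ", "), call. = FALSE)
  }
  map <- data.frame(source = trimws(map$source), target = trimws(map$target),
                    stringsAsFactors = FALSE)
  map[!duplicated(map), , drop = FALSE]
}

#' Read a gene-to-category map (modules, risk lists, tissue panels)
#'
#' @param path TSV with columns `gene` and `category`.
#' @return Named list mapping each category to its member gene set.
#' @export
read_category_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("gene", "category") %in% names(df))) {
    stop("category map must have columns `gene` and `category`", call. = FALSE)
  }
  lapply(split(trimws(df$gene), df$category), unique)
}

#' Read a per-gene feature table
#'
#' Expected columns (any subset, by exact name): `pli`, `mutation_probability`,
#' `haploinsufficiency`, `transcript_length`, `gims`, plus `gene`.
#'
#' @param path TSV file.
#' @return A data.frame keyed by the `gene` column.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene" %in% names(df)) stop("feature table must have a `gene` column", call. = FALSE)
  df$gene <- trimws(df$gene)
  if ("pli" %in% names(df)) {
    pli <- df$pli[!is.na(df$pli)]
    if (length(pli) && (min(pli) < 0 || max(pli) > 1)) {
      stop("pLI values must lie in [0, 1]", call. = FALSE)
    }
  }
  if ("transcript_length" %in% names(df)) {
    tl <- df$transcript_length[!is.na(df$transcript_length)]
    if (length(tl) && any(tl <= 0 | tl != round(tl))) {
      stop("transcript lengths must be positive integers", call. = FALSE)
    }
  }
  df[!duplicated(df$gene), , drop = FALSE]
}

#' Read a per-gene class-specific mutation-rate table
#'
#' The loss-of-function class is either a single `p_lof` column or the sum of
#' `p_non`, `p_frameshift` and `p_splice`; the protein-altering class is the
#' `p_mis` missense column.
#'
#' @param path TSV file with a `gene` column plus rate columns.
#' @return A data.frame with columns `gene`, `p_lof`, `p_protein_altering`.
#' @export
read_rate_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene" %in% names(df)) stop("rate table must have a `gene` column", call. = FALSE)
  lof <- if ("p_lof" %in% names(df)) {
    as.numeric(df$p_lof)
  } else if (all(c("p_non", "p_frameshift", "p_splice") %in% names(df))) {
    as.numeric(df$p_non) + as.numeric(df$p_frameshift) + as.numeric(df$p_splice)
  } else {
    stop("rate table needs `p_lof` or all of `p_non`, `p_frameshift`, `p_splice`",
         call. = FALSE)
  }
  if (!"p_mis" %in% names(df)) stop("rate table needs a `p_mis` column", call. = FALSE)
  out <- data.frame(gene = trimws(df$gene), p_lof = lof,
                    p_protein_altering = as.numeric(df$p_mis),
                    stringsAsFactors = FALSE)
  if (any(out$p_lof < 0, na.rm = TRUE) || any(out$p_protein_altering < 0, na.rm = TRUE)) {
    stop("mutation rates must be non-negative", call. = FALSE)
  }
  out[!duplicated(out$gene), , drop = FALSE]
}

#' Write a data.frame as TSV
#'
#' Floating-point columns are written at 6 significant digits; full precision
#' is kept internally and only rounded at the output boundary.
#'
#' @param df A data.frame.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
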