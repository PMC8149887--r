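# Run configuration: a validated, serialisable bag of the analysis constants.

.config_fields <- c(
  "seed", "n_permutations", "alpha", "p_column", "fisher_sidedness",
  "soft_power", "min_module_size", "merge_threshold", "neglog10_floor"
)

#' Analysis run configuration
#'
#' Central container for the tunable constants of the pipeline. Defaults are
#' the study conditions: 1000 permutations for the size-matched null, FDR
#' threshold 0.05, soft-thresholding power 15, minimum module size 30 and
#' eigengene merge threshold 0.9.
#'
#' @param seed Integer seed applied to every stochastic step.
#' @param n_permutations Number of size-matched null draws.
#' @param alpha FDR significance threshold.
#' @param p_column Which DE p-value feeds the -log10 comparison: `"raw"` or
#'   `"adjusted"`. Both are supported because raw p-values enter the rank
#'   tests while figures are often drawn on the adjusted scale.
#' @param fisher_sidedness `"greater"` (enrichment, default) or `"two-sided"`.
#' @param soft_power Exponent of the signed soft-thresholded adjacency.
#' @param min_module_size Smallest co-expression module retained.
#' @param merge_threshold Eigengene correlation above which modules merge.
#' @param neglog10_floor Smallest representable p before the -log10
#'   transform; p below it (including 0) maps to `-log10(neglog10_floor)`.
#' @return An object of class `ess_config`.
#' @examples
#' cfg <- ess_config(seed = 7)
#' cfg$soft_power
#' @export
ess_config <- function(seed = 1L,
                       n_permutations = 1000L,
                       alpha = 0.05,
                       p_column = c("raw", "adjusted"),
                       fisher_sidedness = c("greater", "two-sided"),
                       soft_power = 15,
                       min_module_size = 30L,
                       merge_threshold = 0.9,
                       neglog10_floor = 1e-300) {
  cfg <- list(
    seed = check_count(seed, "seed"),
    n_permutations = check_count(n_permutations, "n_permutations", min = 1L),
    alpha = check_number(alpha, "alpha", min = 0, max = 1),
    p_column = match.arg(p_column),
    fisher_sidedness = match.arg(fisher_sidedness),
    soft_power = check_number(soft_power, "soft_power", min = .Machine$double.eps),
    min_module_size = check_count(min_module_size, "min_module_size", min = 1L),
    merge_threshold = check_number(merge_threshold, "merge_threshold",
                                   min = 1e-12, max = 1),
    neglog10_floor = check_number(neglog10_floor, "neglog10_floor",
                                  min = .Machine$double.xmin, max = 1)
  )
  structure(cfg, class = "ess_config")
}

#' @export
print.ess_config <- function(x, ...) {
  cat("esscomp run configuration\n")
  for (f in .config_fields) cat(sprintf("  %-16s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Read a run configuration from YAML or JSON
#'
#' Unknown keys are rejected so that typos cannot silently fall back to
#' defaults; missing keys take their defaults.
#'
#' @param path File ending in `.yaml`/`.yml` or `.json`.
#' @return An `ess_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  values <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(values), .config_fields)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(ess_config, values)
}

#' Write a run configuration
#'
#' @param config An `ess_config`.
#' @param path Destination; `.json` selects JSON, anything else YAML.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ess_config"))
  values <- unclass(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(values, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(values, path)
  }
  invisible(path)
}

# Stable content hash of a configuration, for run logs.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
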