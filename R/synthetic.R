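# Seeded synthetic-data generators with planted ground truth. Each
# generator is a pure function of (parameters, seed) and returns its data
# together with a `truth` record, so every pipeline stage can be scored
# against what was planted. Defaults emulate the shapes of the real study:
# essential sets of 3838 and 2149 genes sharing 698, DE tables whose
# -log10 p distributions differ by a planted effect within one fold-change
# direction, developmental expression with three temporal module patterns,
# per-gene de novo mutation rates with a planted enrichment factor, and
# feature tables / risk lists with planted shifts and odds ratios.

#' Generate two overlapping essential-gene sets
#'
#' Draws two sets with exactly the requested sizes and overlap from a
#' synthetic gene universe. Defaults reproduce the screen-list shape:
#' 3838 and 2149 genes with 698 in common inside a universe of 20000.
#'
#' @param n_a,n_b Set sizes.
#' @param n_shared Size of the intersection.
#' @param universe_size Number of genes in the universe.
#' @param seed Integer seed.
#' @return A list with `set_a`, `set_b`, `universe` and `truth`.
#' @export
gen_essential_sets <- function(n_a = 3838L, n_b = 2149L, n_shared = 698L,
                               universe_size = 20000L, seed = 1L) {
  n_a <- check_count(n_a, "n_a", min = 1L)
  n_b <- check_count(n_b, "n_b", min = 1L)
  n_shared <- check_count(n_shared, "n_shared")
  universe_size <- check_count(universe_size, "universe_size", min = 1L)
  seed <- check_count(seed, "seed")
  if (n_shared > min(n_a, n_b)) {
    stop("`n_shared` cannot exceed the smaller set size", call. = FALSE)
  }
  if (n_a + n_b - n_shared > universe_size) {
    stop(sprintf("universe too small: need %d distinct genes, have %d",
                 n_a + n_b - n_shared, universe_size), call. = FALSE)
  }
  universe <- sprintf("G%05d", seq_len(universe_size))
  withr::with_seed(seed, {
    picked <- sample(universe, n_a + n_b - n_shared)
    shared <- picked[seq_len(n_shared)]
    a_only <- picked[seq.int(n_shared + 1L, length.out = n_a - n_shared)]
    b_only <- picked[seq.int(n_a + 1L, length.out = n_b - n_shared)]
  })
  list(set_a = c(shared, a_only), set_b = c(shared, b_only), universe = universe,
       truth = list(n_a = n_a, n_b = n_b, n_shared = n_shared,
                    universe_size = universe_size, seed = seed))
}

#' Mean shift on the -log10 p scale for a target Cohen's d
#'
#' Background `-log10(p)` scores of uniform p-values follow an exponential
#' distribution with rate `ln 10` (SD `1 / ln 10`), so a planted mean shift
#' of `delta = d / ln 10` yields pooled-SD Cohen's d of exactly `d`.
#'
#' @param d Target Cohen's d.
#' @return The shift `delta` on the -log10 p scale.
#' @export
delta_for_cohens_d <- function(d) d / log(10)

#' Generate a DE table with a planted directional effect
#'
#' Background `-log10(p)` scores are Exponential with mean `1 / ln 10`
#' (equivalently p ~ Uniform(0, 1)); fold-change signs are Bernoulli(0.5)
#' independent of p, with standard-normal magnitudes. Target-set genes whose
#' fold change lies in the chosen direction have their score shifted by
#' `+delta`, which plants a pooled-SD Cohen's d of `delta * ln 10` against
#' any unshifted group. Adjusted p-values are BH over the whole table.
#'
#' @param universe Character vector of gene identifiers.
#' @param target_set Genes receiving the planted effect.
#' @param direction `"down"` or `"up"`: the fold-change direction carrying
#'   the effect.
#' @param delta Non-negative shift on the -log10 p scale
#'   (see [delta_for_cohens_d()]).
#' @param seed Integer seed.
#' @return A list with `table` (data.frame `gene`, `log2fc`, `pvalue`,
#'   `padj`) and `truth` (including the implied Cohen's d).
#' @export
gen_de_table <- function(universe, target_set = character(0),
                         direction = c("down", "up"), delta = 0, seed = 1L) {
  direction <- match.arg(direction)
  delta <- check_number(delta, "delta", min = 0)
  seed <- check_count(seed, "seed")
  if (!all(target_set %in% universe)) {
    stop("`target_set` must be a subset of `universe`", call. = FALSE)
  }
  n <- length(universe)
  withr::with_seed(seed, {
    score <- stats::rexp(n, rate = log(10))
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    magnitude <- abs(stats::rnorm(n))
  })
  want_sign <- if (direction == "up") 1 else -1
  hit <- universe %in% target_set & sgn == want_sign
  score[hit] <- score[hit] + delta
  pvalue <- 10^(-score)
  table <- data.frame(gene = universe, log2fc = sgn * magnitude,
                      pvalue = pvalue, padj = bh_adjust(pvalue),
                      stringsAsFactors = FALSE)
  list(table = table,
       truth = list(direction = direction, delta = delta,
                    implied_d = delta * log(10), n_target_hit = sum(hit),
                    seed = seed))
}

# Temporal eigengene templates on a prenatal progression q in [0, 1] plus a
# postnatal plateau; values are in arbitrary expression units.
.pattern_templates <- list(
  prenatal_rise_sustained = function(q, prenatal) ifelse(prenatal, 2 * q - 1, 1),
  low_prenatal_mid = function(q, prenatal) ifelse(prenatal, -1, 0),
  prenatal_high_drop = function(q, prenatal) ifelse(prenatal, 1 - 2 * q, -1)
)

#' Generate a developmental expression matrix with planted modules
#'
#' Plants one module per requested pattern: each module gene is
#' `loading * template(sample) + noise`, with loadings uniform in
#' [0.5, 1] and per-gene Gaussian noise SD equal to the gene's signal SD
#' divided by `snr`. Background genes are pure standard-normal noise.
#' Prenatal ages are uniform over 56-260 post-conception days and
#' postnatal ages log-uniform up to 70 years, emulating a full
#' developmental series.
#'
#' @param module_sizes Integer vector of module sizes (each >= 2).
#' @param pattern_labels One temporal pattern per module, from
#'   `"prenatal_rise_sustained"`, `"low_prenatal_mid"`,
#'   `"prenatal_high_drop"`.
#' @param n_prenatal,n_postnatal Sample counts on each side of birth.
#' @param snr Per-gene signal-to-noise ratio (signal SD / noise SD).
#' @param n_background Number of pure-noise genes.
#' @param seed Integer seed.
#' @return A list with `expr` (an [expression_matrix()]) and `truth`
#'   (planted `assignment`, `patterns`, `templates`).
#' @export
gen_expression <- function(module_sizes = c(60L, 50L, 40L),
                           pattern_labels = c("prenatal_rise_sustained",
                                              "low_prenatal_mid",
                                              "prenatal_high_drop"),
                           n_prenatal = 20L, n_postnatal = 20L, snr = 3,
                           n_background = 150L, seed = 1L) {
  if (length(module_sizes) != length(pattern_labels)) {
    stop("`module_sizes` and `pattern_labels` must have equal length", call. = FALSE)
  }
  if (any(module_sizes < 2L)) stop("each module needs >= 2 genes", call. = FALSE)
  if (length(pattern_labels)) {
    pattern_labels <- match.arg(pattern_labels, names(.pattern_templates),
                                several.ok = TRUE)
  }
  n_prenatal <- check_count(n_prenatal, "n_prenatal", min = 3L)
  n_postnatal <- check_count(n_postnatal, "n_postnatal", min = 3L)
  snr <- check_number(snr, "snr", min = .Machine$double.eps)
  n_background <- check_count(n_background, "n_background")
  seed <- check_count(seed, "seed")

  n_genes <- sum(module_sizes) + n_background
  gene_ids <- sprintf("EG%04d", seq_len(n_genes))
  sample_ids <- sprintf("S%03d", seq_len(n_prenatal + n_postnatal))
  withr::with_seed(seed, {
    age_pre <- sort(stats::runif(n_prenatal, 56, 260))
    age_post <- sort(exp(stats::runif(n_postnatal, log(270), log(266 + 70 * 365))))
    age <- c(age_pre, age_post)
    prenatal <- c(rep(TRUE, n_prenatal), rep(FALSE, n_postnatal))
    q <- rep(0, length(age))
    q[prenatal] <- (age_pre - 56) / (260 - 56)
    templates <- vapply(pattern_labels,
                        function(p) .pattern_templates[[p]](q, prenatal),
                        numeric(length(age)))
    values <- matrix(0, nrow = n_genes, ncol = length(age),
                     dimnames = list(gene_ids, sample_ids))
    assignment <- integer(n_genes)
    row <- 0L
    for (m in seq_along(module_sizes)) {
      sz <- module_sizes[[m]]
      loadings <- stats::runif(sz, 0.5, 1)
      signal <- outer(loadings, templates[, m])
      noise_sd <- apply(signal, 1, stats::sd) / snr
      noise <- matrix(stats::rnorm(sz * length(age)), nrow = sz) * noise_sd
      values[row + seq_len(sz), ] <- signal + noise
      assignment[row + seq_len(sz)] <- m
      row <- row + sz
    }
    if (n_background > 0L) {
      values[row + seq_len(n_background), ] <-
        matrix(stats::rnorm(n_background * length(age)), nrow = n_background)
    }
  })
  names(assignment) <- gene_ids
  expr <- expression_matrix(values, age, prenatal)
  list(expr = expr,
       truth = list(assignment = assignment,
                    patterns = stats::setNames(pattern_labels,
                                               sprintf("M%d", seq_along(pattern_labels))),
                    templates = templates, snr = snr,
                    module_sizes = module_sizes, seed = seed))
}

#' Generate a de novo mutation model with a planted enrichment factor
#'
#' Per-gene class-specific mutation probabilities are drawn log-uniform in
#' [1e-6, 1e-4]; observed counts are Poisson with mean
#' `2 * n_trios * p_g * gamma` inside the chosen gene set and factor 1
#' outside, summed per set and class.
#'
#' @param rate_table_size Number of genes in the rate table.
#' @param set_size Size of the tested gene set (drawn at random from the
#'   table).
#' @param n_trios Number of trios (> 0).
#' @param gamma Planted enrichment factor (>= 0); 1 means no enrichment.
#' @param seed Integer seed.
#' @return A list of class `denovo_model` with `rates`, `set`, `n_trios`,
#'   `observed` (named counts per class) and `truth`.
#' @export
gen_denovo <- function(rate_table_size = 1000L, set_size = 50L, n_trios = 2500L,
                       gamma = 1, seed = 1L) {
  rate_table_size <- check_count(rate_table_size, "rate_table_size", min = 1L)
  set_size <- check_count(set_size, "set_size", min = 1L)
  n_trios <- check_count(n_trios, "n_trios", min = 1L)
  gamma <- check_number(gamma, "gamma", min = 0)
  seed <- check_count(seed, "seed")
  if (set_size > rate_table_size) {
    stop("`set_size` cannot exceed `rate_table_size`", call. = FALSE)
  }
  genes <- sprintf("DG%05d", seq_len(rate_table_size))
  withr::with_seed(seed, {
    rates <- data.frame(
      gene = genes,
      p_lof = 10^stats::runif(rate_table_size, -6, -4),
      p_protein_altering = 10^stats::runif(rate_table_size, -6, -4),
      stringsAsFactors = FALSE
    )
    set <- sample(genes, set_size)
    in_set <- genes %in% set
    factor <- ifelse(in_set, gamma, 1)
    counts_lof <- stats::rpois(rate_table_size, 2 * n_trios * rates$p_lof * factor)
    counts_pa <- stats::rpois(rate_table_size,
                              2 * n_trios * rates$p_protein_altering * factor)
  })
  observed <- c(lof = sum(counts_lof[in_set]),
                protein_altering = sum(counts_pa[in_set]))
  structure(
    list(rates = rates, set = set, n_trios = n_trios, observed = observed,
         truth = list(gamma = gamma,
                      lambda_null = c(
                        lof = 2 * n_trios * sum(rates$p_lof[in_set]),
                        protein_altering = 2 * n_trios *
                          sum(rates$p_protein_altering[in_set])),
                      seed = seed)),
    class = "denovo_model"
  )
}

#' Generate a per-gene feature table with a planted distribution shift
#'
#' Each feature is derived from an independent standard-normal latent that
#' is shifted by `shift` (in SD units) for target-set genes: pLI and
#' haploinsufficiency through a logistic transform into [0, 1], mutation
#' probability and transcript length through log-normal transforms, and a
#' selection z-score (`gims`) on the latent scale itself (so the planted
#' Cohen's d on `gims` equals `shift`).
#'
#' @param universe Character vector of gene identifiers.
#' @param target_set Genes receiving the shift.
#' @param shift Latent-scale location shift (finite).
#' @param seed Integer seed.
#' @return A list with `table` (data.frame of features) and `truth`.
#' @export
gen_feature_table <- function(universe, target_set = character(0), shift = 0,
                              seed = 1L) {
  shift <- check_number(shift, "shift")
  seed <- check_count(seed, "seed")
  n <- length(universe)
  offset <- (universe %in% target_set) * shift
  withr::with_seed(seed, {
    lat <- function() stats::rnorm(n) + offset
    table <- data.frame(
      gene = universe,
      pli = stats::plogis(1.7 * lat()),
      mutation_probability = 10^(-4.5 + 0.5 * lat()),
      haploinsufficiency = stats::plogis(lat()),
      transcript_length = pmax(1, round(10^(3.4 + 0.35 * lat()))),
      gims = lat(),
      stringsAsFactors = FALSE
    )
  })
  list(table = table, truth = list(shift = shift, seed = seed))
}

#' Generate risk-gene lists with planted odds ratios
#'
#' Each list includes non-target genes with probability `baseline_rate` and
#' target-set genes with the probability implied by the planted odds ratio,
#' so the expected 2x2 table has odds ratio `odds_ratio`.
#'
#' @param universe Character vector of gene identifiers.
#' @param target_set Genes with elevated membership odds.
#' @param odds_ratio Planted odds ratio (> 0).
#' @param baseline_rate Membership probability outside the target set.
#' @param n_lists Number of lists to generate.
#' @param seed Integer seed.
#' @return A list with `categories` (data.frame `gene`, `category`) and
#'   `truth`.
#' @export
gen_risk_lists <- function(universe, target_set = character(0), odds_ratio = 1,
                           baseline_rate = 0.02, n_lists = 1L, seed = 1L) {
  odds_ratio <- check_number(odds_ratio, "odds_ratio", min = .Machine$double.eps)
  baseline_rate <- check_number(baseline_rate, "baseline_rate", min = 0, max = 1)
  n_lists <- check_count(n_lists, "n_lists", min = 1L)
  seed <- check_count(seed, "seed")
  p0 <- baseline_rate
  p1 <- odds_ratio * p0 / (1 - p0 + odds_ratio * p0)
  prob <- ifelse(universe %in% target_set, p1, p0)
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_lists), function(l) {
      members <- universe[stats::runif(length(universe)) < prob]
      if (length(members) == 0L) return(NULL)
      data.frame(gene = members, category = sprintf("risk_list_%d", l),
                 stringsAsFactors = FALSE)
    })
  })
  list(categories = do.call(rbind, rows),
       truth = list(odds_ratio = odds_ratio, baseline_rate = baseline_rate,
                    target_rate = p1, n_lists = n_lists, seed = seed))
}
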