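Package: esscomp
Title: Comparative Analysis of Essential Gene Sets from Genome-Wide Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for comparing two essential-gene sets (for example an in vivo
    neuronal screen versus cancer-cell-line screens) across differential-expression,
    co-expression, genetic-risk, and gene-feature evidence. Implements three-way set
    partition after ortholog mapping, directional comparison of -log10 p-value
    distributions by two-sided Wilcoxon rank-sum tests with pooled-SD Cohen's d and a
    size-matched permutation null, simplified signed weighted co-expression network
    analysis (soft-thresholded adjacency, topological overlap, module eigengenes,
    eigengene merging, temporal-pattern classification), Fisher's exact enrichment with
    Benjamini-Hochberg correction, a Poisson expectation test for de novo mutation
    burden, per-gene feature comparisons, and seeded synthetic-data generators with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
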