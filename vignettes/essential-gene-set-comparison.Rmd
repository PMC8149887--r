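---
title: "Comparing essential gene sets: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing essential gene sets: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esscomp)
```

## The scientific problem

Genome-wide knock-out and knock-down screens define *essential genes*: genes
whose loss kills the cell or organism. Screens run in cancer cell lines
(yielding "common essential" genes) and screens run in vivo in post-mitotic
neuronal tissue (yielding "neuronal essential" genes) capture overlapping but
distinct biology. `esscomp` provides the statistical machinery to contrast two
such sets across four independent lines of evidence:

1. **Differential expression (DE)** in case–control brain transcriptomes:
   do genes of one set show systematically stronger DE signal than the other?
2. **Developmental co-expression**: do the sets live in different
   co-expression modules of the developing brain, with different temporal
   trajectories?
3. **Genetic risk**: are the sets enriched in risk-gene lists, and do they
   carry more de novo mutations in patients than the mutational target size
   predicts?
4. **Gene-level features**: constraint (pLI), mutation probability,
   haploinsufficiency, transcript length, selection metrics.

The package consumes standard upstream outputs (DE tables from tools such as
DESeq2, published per-gene rate and feature tables) and never recomputes them;
its own contribution is the comparative statistics downstream, plus seeded
generators that simulate every input with planted ground truth so that each
statistic can be validated end to end.

## Set partition

After mapping the in vivo screen list to human symbols with an ortholog table
(`map_orthologs()`; one-to-many orthology expands, many-to-one collapses by
union — a deterministic rule that avoids arbitrary best-hit choices),
`partition_sets()` performs exact set algebra: A-specific, B-specific and
shared blocks. With screen-shaped inputs of 3838 and 2149 genes sharing 698,
the specific blocks have 3140 and 1451 genes. All identifier matching is
exact and case-sensitive; no alias resolution is attempted, favouring
reproducibility over recall.

## The directional DE comparison

Each DE table is split by fold-change direction (`split_by_direction()`);
genes with zero or missing fold change, or a missing selected p-value, are
excluded with logged counts. Within a direction, each gene's evidence is
summarised as $-\log_{10} p$, with $p$ floored at `neglog10_floor`
($10^{-300}$ by default) so that underflowed p-values of 0 map to a finite
score of 300. Both the raw and the BH-adjusted p-value are supported as the
compared quantity (`p_column`); raw is the default, adjusted is one switch
away, and no claim is made that either is uniquely "the" scale — the rank
test is invariant to any monotone rescaling shared by both groups, so the
choice mainly affects the effect size.

`compare_gene_sets()` then contrasts the two *specific* blocks (genes in both
sets are excluded from both samples) with:

* a **two-sided Wilcoxon rank-sum test** — exact enumeration (via the exact
  null distribution of the Mann–Whitney statistic) when the pooled sample has
  at most 20 untied observations, otherwise the normal approximation with tie
  correction and continuity correction. The exact two-sided p is defined as
  $\min(1,\, 2\min(P(W \le w), P(W \ge w)))$ with both tails inclusive, which
  is what exhaustive enumeration over rank assignments gives; ties always use
  the approximation.
* **pooled-SD Cohen's d**,
  $d = (\bar Y - \bar X)/s$ with
  $s = \sqrt{\tfrac{(n_X-1)s_X^2 + (n_Y-1)s_Y^2}{n_X+n_Y-2}}$,
  the pooled form because the two groups have unequal sizes. Positive $d$
  means the first set shows stronger DE signal.

### The size-matched permutation null

A significant Wilcoxon p alone does not show that *essentiality* drives the
difference. `permutation_null()` draws, per iteration, two **disjoint**
random gene sets of the observed sizes from the nonessential pool (genes in
the slice belonging to neither input set), reruns the comparison and stores
the p-value; 1000 iterations by default. The observed comparison is placed on
this distribution by its empirical quantile. Each direction gets its own
null rather than pooling across directions, matching the per-direction
observed tests. Sampling is without replacement and the two draws never
overlap within an iteration, mimicking the disjoint specific blocks.

## Co-expression modules

The module pipeline is a deliberately compact signed weighted co-expression
analysis:

* **Adjacency** $a_{ij} = ((1 + \mathrm{cor}_{ij})/2)^\beta$ with
  $\beta = 15$: a *signed* network, so anti-correlated genes get adjacency
  near 0 rather than near 1. Correlation is Pearson by default; biweight
  midcorrelation (tuning constant 9 median absolute deviations, with a
  Pearson fallback for zero-MAD genes) is available for outlier-heavy data.
* **Topological overlap**
  $\omega_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i,k_j) + 1 - a_{ij})$,
  computed by matrix products and checked in the tests against a naive
  double-loop evaluation to $10^{-10}$.
* **Module detection**: average-linkage clustering of $1-\omega$ with a
  **static cut**. The published dynamic tree-cut algorithm is an external
  method and is not reimplemented here; the analysis surface that matters
  downstream — enrichment and temporal patterns — is robust to the cut. The
  default `cut_height = 0.75` sits midway between typical within-module
  dissimilarities (≈ 0.5 under the default network) and the background
  (≈ 1.0). A consequence worth knowing: module counts will generally *not*
  match analyses that used the dynamic cut, and strongly correlated planted
  trajectories occasionally merge at this height.
* **Eigengenes**: first principal component of the gene-standardized module
  submatrix, unit-norm per-sample scores, sign oriented so the correlation
  with the module's mean standardized expression is non-negative — without
  a sign convention, "rising" versus "falling" trajectories would be
  arbitrary. Modules whose eigengenes correlate above `merge_threshold = 0.9`
  are merged iteratively (highest pair first, smaller label wins ties,
  eigengene recomputed after each merge) to a fixpoint.
* **Temporal patterns**: the standardized eigengene is summarised in three
  windows — first prenatal third, last prenatal third (sample-count thirds of
  the age-ordered prenatal samples, robust to irregular age sampling) and
  postnatal. With margin $\delta = 0.25$ SD, the decision rules are:
  rise (late − early > $\delta$) and sustained (postnatal ≥ late − $\delta$)
  → `prenatal_rise_sustained`; fall (late − early < −$\delta$) without a
  postnatal rebound → `prenatal_high_drop`; flat prenatal with a postnatal
  increase > $\delta$ → `low_prenatal_mid`; anything else `unclassified`.
  Classification needs at least 3 prenatal and 3 postnatal samples.

## Enrichment and de novo burden

`fisher_exact()` implements the hypergeometric one-sided "greater" tail
(the default, since module/risk/tissue questions are enrichment questions)
and the standard two-sided sum of no-more-probable tables; the odds ratio
reported is the sample odds ratio $ad/bc$, with `Inf` flagged explicitly when
a zero cell demands it. `set_enrichment()` runs one test per category against
a fixed universe and applies Benjamini–Hochberg correction across categories
(through `stats::p.adjust`), flagging categories at FDR `alpha = 0.05`. For
module enrichment the natural universe is every gene that entered the network
(assigned or not); the universe is always an explicit argument, never
implicit.

The de novo test uses the classical expectation model: for mutation class $c$
(loss-of-function = nonsense + frameshift + canonical splice; protein-altering
= missense) the expected count in a gene set is
$\lambda = 2\, n_{\text{trios}} \sum_{g} p_{g,c}$, and the observed count is
compared by the Poisson upper tail $P(X \ge \text{obs} \mid \lambda)$. Note
that this p-value is *discrete*: at moderate $\lambda$ it cannot be uniform
under the null, only super-uniform, so calibration is assessed as type-I
error at most the nominal level rather than by a continuous-uniformity test.

## The synthetic-data generators

Every generator is a pure function of its parameters and an integer seed
(the same call is bit-identical), and returns the planted truth alongside the
data. Defaults are fixed at the study conditions and are not tuning knobs:

* `gen_essential_sets()`: 3838/2149/698 within a 20000-gene universe.
* `gen_de_table()`: background $-\log_{10} p \sim \mathrm{Exp}(\ln 10)$ —
  exactly the transform of uniform p-values, so the planted shift `delta` is
  a mean shift on the analysis scale and the implied Cohen's d is
  `delta * ln 10` (helper `delta_for_cohens_d()`). Fold-change signs are fair
  coins independent of p; magnitudes are standard normal and irrelevant to
  the analysis, which uses only their sign.
* `gen_expression()`: three planted modules (60/50/40 genes) on the three
  temporal templates, 150 pure-noise background genes, 20 prenatal (56–260
  post-conception days, uniform) and 20 postnatal samples (log-uniform to 70
  years), per-gene loadings in [0.5, 1] and noise SD = signal SD / `snr`
  with `snr = 3`.
* `gen_denovo()`: per-gene class rates log-uniform in $[10^{-6}, 10^{-4}]$,
  1000 genes, a 50-gene test set and 2500 trios (null $\lambda \approx 5$);
  counts Poisson with the enrichment factor $\gamma$ inside the set.
* `gen_feature_table()` / `gen_risk_lists()`: features derived from shifted
  standard-normal latents (pLI and haploinsufficiency through a logistic
  transform, mutation probability and transcript length log-normal, `gims`
  on the latent scale so its planted d equals the shift); risk-list
  membership sampled at the rate implied by the planted odds ratio.

What the generators deliberately do **not** emulate: negative-binomial read
counts and the DE model fit itself (DE tables are consumed, not computed),
batch effects, correlated features, LD structure, and realistic gene-length
confounding of de novo rates. Passing the recovery suites therefore shows
that the *statistics* behave as designed under their stated models — not
that any particular biological dataset will reproduce a given figure.

## Problem sizes and numerical choices in the test suite

The validation suites run the calibration study at 1000 simulated DE tables
(20000 genes each), the effect-recovery study at 20 seeds with slice sizes
near 3000 vs 1500, the permutation null at 1000 iterations, the module
recovery study at 10 seeds of the 300-gene preset, and the de novo power and
calibration studies at 500 replicates each — sizes chosen so the whole suite
completes in about a minute on one core while keeping Monte-Carlo error well
inside the tested bands. Exhaustive oracles (all rank assignments up to
pooled size 10; all fixed-margin 2×2 tables up to total 40) back the exact
branches.

Known limitations: the static cut trades module-count fidelity for
simplicity; eigengene merging uses signed (not absolute) correlation, so
anti-correlated modules never merge; the Wilcoxon exact branch is skipped
whenever ties are present; and ortholog expansion can inflate set sizes when
the map is highly one-to-many — the partition is computed after mapping, so
reported counts always refer to the mapped space.
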