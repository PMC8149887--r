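# esscomp

Comparative analysis of two essential-gene sets — for example neuronal
essential genes from an in vivo brain screen versus common essential genes
from cancer-cell-line screens — across differential expression,
developmental co-expression, genetic risk and gene-level features.

Genome-wide screens disagree about what is "essential" depending on the
cellular context. Given two gene sets A and B, `esscomp` partitions them into
A-specific, B-specific and shared blocks and asks, for the specific blocks:

* **Differential expression.** Within each fold-change direction of a
  case–control DE table, compare the two sets' −log10 *p* distributions with
  a two-sided Wilcoxon rank-sum test and a pooled-SD Cohen's *d*,

  d = (Ȳ − X̄) / s,  s = √(((n_X − 1)s²_X + (n_Y − 1)s²_Y) / (n_X + n_Y − 2)),

  and calibrate against a size-matched permutation null: repeatedly draw two
  disjoint random sets of the same sizes from the nonessential gene pool and
  rerun the test (1000 iterations by default).
* **Co-expression.** Build a signed weighted network (adjacency
  ((1 + cor)/2)^β, β = 15), transform it to topological overlap, cluster
  1 − TOM (average linkage, static cut), summarise each module ≥ 30 genes by
  its eigengene (first PC, sign-oriented), merge modules whose eigengenes
  correlate > 0.9, and classify each trajectory as prenatal-rise-sustained,
  low-prenatal-mid, or prenatal-high-drop.
* **Risk enrichment.** Fisher's exact test (one-sided "greater" by default)
  of a set against module memberships, risk-gene lists or tissue panels,
  with Benjamini–Hochberg correction at FDR 0.05.
* **De novo burden.** Poisson expectation test with
  λ = 2 · n_trios · Σ_g p_g per mutation class (loss-of-function,
  protein-altering), p = P(X ≥ observed | λ).
* **Features.** Wilcoxon + Cohen's *d* comparisons of pLI, mutation
  probability, haploinsufficiency, transcript length and selection scores.

A synthetic-data module (`gen_*` functions) generates every input with
planted ground truth — set sizes and overlap, directional effect sizes,
module structure and temporal patterns, de novo enrichment factors, feature
shifts, risk-list odds ratios — so the whole pipeline is testable end to end.

## Worked example

`run_synthetic_benchmark()` simulates every input, analyzes each with the
corresponding module and scores the results against the planted truth:

```r
library(esscomp)
bm <- run_synthetic_benchmark(seed = 1, n_perm = 200)
print(bm)
#> synthetic benchmark (seed 1)
#>   partition: 3140 / 1451 / 698 (A-specific / B-specific / shared)
#>   DE effect: planted d = 0.300, recovered d = 0.385, Wilcoxon p = 1.32e-34
#>   permutation empirical quantile = 0
#>   module recovery ARI = 1.000; 3/3 temporal patterns recovered
#>   de novo p (lof / protein-altering) = 0.0113 / 9.22e-05
#>   feature `gims` d = 0.495 (p = 1.6e-50)
#>   risk list q = 1.39e-81 (significant)
```

Reading the output: two sets of 3838 and 2149 genes sharing 698 partition
into 3140 and 1451 specific genes; a Cohen's d of 0.3 planted in the
down-regulated direction is recovered (single-seed estimates scatter around
the target; the 20-seed average in the acceptance run lands within ±0.05) and
the observed Wilcoxon p sits below every one of the 200 size-matched null
draws; the three planted co-expression modules are recovered exactly
(adjusted Rand index 1.0) along with all three temporal patterns; the planted
3× de novo enrichment, the 0.5 SD feature shift and the odds-ratio-5 risk
list are all detected.

The same operations are scriptable from a shell via the bundled CLI
(`inst/cli/esscomp`), with subcommands `simulate`, `partition`, `compare-de`,
`modules`, `enrich`, `denovo` and `features`; every run writes TSV outputs
plus a `run_log.json` and is byte-identical for a fixed seed.

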