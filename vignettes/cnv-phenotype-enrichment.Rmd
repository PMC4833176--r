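---
title: "CNV gene assignment, phenotype enrichment and co-expression connectivity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CNV gene assignment, phenotype enrichment and co-expression connectivity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cnvphen` chains four analyses that are usually scattered across ad-hoc
scripts: assigning genes to copy-number variants (CNVs), annotating those
genes with mouse-knockout phenotypes under ontology closure, testing
per-phenotype enrichment with FDR control, and testing the co-expression
connectivity of the implicated gene sets by permutation. This vignette
records the model, the assumptions, every tunable that matters, and the
design decisions taken where the methodology left genuine freedom.

## 1. Coordinates and gene assignment

All intervals are held internally as 0-based half-open `[start, end)`
(the BED convention); `read_cnvs()` converts 1-based inclusive tables on
load and `chr` prefixes are stripped. Overlap is strand-agnostic — CNVs
are unstranded events.

The two dosage classes get deliberately asymmetric rules:

* **Gains** (`assign_gain_genes`): the gene's span — the union of all its
  transcripts, minimum exon start to maximum exon end — must be fully
  contained in the CNV. Rationale: a partially duplicated gene does not
  yield an extra functional copy, and span containment implies
  containment of every transcript, so the "whole gene" and "every
  transcript" readings coincide.
* **Losses** (`assign_loss_genes`): the CNV must overlap, by at least one
  base, a coding (CDS) segment of *every coding transcript*. Untranslated
  regions do not count, and non-coding isoforms are excluded from the
  quantifier — a deletion cannot disrupt a coding exon that does not
  exist. A gene with no coding transcript is never a loss-gene. This
  targets disruption of the protein product whichever isoform is
  expressed, and is deliberately stricter in one direction: the same
  interval can qualify a gene as a loss-gene while failing the gain rule.

Case CNVs are restricted to those strictly longer than `min_length_bp`
(default 500,000 bp; a CNV of exactly 500 kb is excluded). Control-cohort
CNVs are **never** length-filtered: `filter_control_genes()` recomputes
control gene sets with the same assignment rules and removes case genes
copy-changed *in the same direction* — a gene gained in a case but only
deleted in controls is retained.

Interval arithmetic is delegated to GenomicRanges; the brute-force
all-pairs oracle lives only in the test suite, where assignment is checked
for equivalence on randomized fixtures, for invariance to row order and
cohort splitting, and for monotonicity (enlarging a gain never removes an
assignment).

## 2. Ontology closure and the annotated universe

Phenotype terms form a DAG (`is_a` edges); `read_obo()` parses OBO 1.2
stanzas, drops obsolete terms, and rejects cyclic graphs naming the cycle.
Orthology is strictly 1:1: one-to-many and many-to-many rows are dropped
with a reported count rather than resolved heuristically, because partial
orthology makes phenotype transfer ambiguous.

`annotate_closure()` maps direct mouse annotations onto human genes and
propagates them rootward in reverse topological order, so a gene annotated
with a term belongs to the closure set of every ancestor. The *universe*
is every human gene with a 1:1 orthologue carrying at least one
annotation; it is independent of which terms are later tested.

`select_test_terms()` returns the descendants of a chosen root whose
closure sets hold at least `min_genes` members, in lexicographic order so
FDR input order is reproducible. The function default is `min_genes = 1`
(every annotated descendant); the pipeline driver
`cnv_phenotype_enrichment()` defaults to `min_genes = 20`. The higher
analysis default is a deliberate choice: closure sets of a handful of
genes produce unstable hypergeometric estimates, and the tiny descendants
of a genuinely enriched term recapture its signal redundantly — in
planted-signal simulations they occasionally outrank their parent on
subset noise alone. Where the selection rule used to produce a published
term list is known, set `min_genes` accordingly.

## 3. Enrichment model

For a term with `K` universe genes, a test set with `n` analyzable genes
(distinct, in-universe) of which `k` are in the term set, and a universe
of size `N`:

* fold enrichment `= (k/n) / (K/N)`, exact internally, rounded to 2
  significant figures only in reports (the convention the motivating
  tables use);
* `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`, computed by
  `stats::phyper` (exact tail summation, log-space stable); the test is
  one-sided for enrichment — depletion shows as fold < 1 but is not
  tested;
* FDR: Storey q-values (smoother π₀: cubic spline of `π₀(λ)` over
  `λ = 0.05…0.95`, evaluated at the largest λ, clamped to `(0, 1]`) or
  Benjamini–Hochberg. Storey's π₀ is noisy for small families, so a
  warning fires below 100 tests and `"bh"` is recommended there.

Degenerate inputs are explicit outcomes, not crashes: an empty analyzable
set returns a zero-row result flagged "no analyzable genes"; `n = 0` or
`K = 0` folds are errors.

## 4. Co-expression network

`filter_expressed()` keeps genes with expression `>= min_rpkm` (default
1 RPKM) in at least `ceiling(min_fraction × samples)` samples (default
5%), both comparisons inclusive. `correlation_matrix()` computes Pearson
correlation across all samples, by default on `log2(x + 1)`: whether to
transform is genuinely open (correlation of raw RPKM is dominated by a few
high-expression genes), so the transform is an argument and the default is
a package decision, not an inherited fact. At least 3 samples are
required; zero-variance genes get `NA` correlations and never form edges.

`threshold_network()` retains edges either by absolute weight
(`r >= value`; negative correlations are never edges — a signed threshold
of 0.7 is inherently one-tailed) or by top fraction
(`floor(value × n_pairs)` strongest pairs, extended through ties at the
boundary with a reported count — deterministic and slightly generous
rather than order-dependent). Both modes report the achieved fraction and
implied cutoff so the "r ≥ 0.7 ≙ strongest 5%" style of cross-check can
be made on any dataset. Filtered and zero-variance genes are absent from
the node set; downstream tests treat absent genes as contributing zero
weight. Nesting across thresholds (relaxing `r` only adds edges) is
asserted in the tests.

The full weighted-network toolkit (soft-power adjacency, topological
overlap) is intentionally not reimplemented: the analyses this package
serves operate on the plain correlation-threshold network, and that
network is what is built.

## 5. Connectivity permutation tests

The statistic is always a summed edge weight: within a set
(`within_set_weight`) or between two disjoint sets
(`between_set_weight`). Sets may legitimately contain genes absent from
the network — they stay in the draw and contribute zero, because "not in
the network" is information, not missingness.

The empirical p-value is `(k + 1)/(n_perm + 1)` with `k` the count of
permutation statistics **greater than or equal to** the observed one:
ties count against the observed statistic, p is never exactly zero, and
with the canonical `n_perm = 100,000` the smallest attainable p is
1/100,001. Null draws are uniform, without replacement, of matched size
from the stated background; a single seeded RNG stream per invocation is
recorded in the result for bit-identical reproducibility.

Three tests share this machinery:

* `cohesion_test(candidates, background)`: are the candidates more
  tightly co-expressed than random same-size subsets of the background?
* `cross_set_test(candidates, target, background)`: are the candidates
  more connected to a fixed target set than random background subsets
  are? Genes shared between candidates and target must be removed — from
  both sets *and* the background — before calling; overlapping inputs are
  an error rather than a silent fix, so the exclusion bookkeeping
  (`exclude_shared()`) is always visible in the analysis script.
* `comparative_background_test(candidates, competitor, target)`: is the
  target more connected to the candidates than to a competitor set? Null
  sets are drawn from the composite background `candidates ∪ competitor`
  after removing target-annotated genes from both and deduplicating the
  overlap; the resulting set sizes are recorded on the result.

Internally the adjacency is sparse and symmetric; for networks up to a
few thousand nodes it is densified inside the permutation loop (submatrix
indexing dominates the cost), and cross-set statistics are reduced to a
sum over precomputed per-gene weights to the fixed target.

## 6. What the synthetic generator emulates — and what it does not

`sim_config()` defaults define one coherent study scale:

| parameter | default | what it mirrors |
|---|---|---|
| `universe_size` (= `n_genes`) | 6,350 | annotated-universe size |
| `focal_term_size` | 439 | focal phenotype closure set |
| `behaviour_term_size` | 2,089 | behavioural category closure |
| `n_focal_children` | 38 | more specific terms under the focal one |
| behavioural terms under the root | 158 | tested-phenotype count |
| `min_cnv_length_bp` | 5×10⁵ bp | the large-CNV cutoff |
| `cnv_length_range` | 2.5×10⁵–2×10⁶ bp, log-uniform | CNV lengths straddling the cutoff |
| `n_case_gains` / `n_case_losses` | 94 / 29 | case cohort scale (see below) |
| `planted_fold` | 3 | planted gain-gene enrichment |
| `within_module_r` | 0.8 | planted co-expression strength |
| `n_samples` | 120 | expression samples |

Design points worth stating explicitly:

* **One gene per CNV.** Gene anchors are spaced 3 Mb apart — beyond the
  maximum simulated CNV — so each case gain contributes exactly its
  anchor gene. This sacrifices the multi-gene structure of real CNVs
  (unit tests cover that combinatorics separately with hand-built
  fixtures) in exchange for an analytically exact planted signal.
* **Planting is defined on the analyzed cohort.** Gain-genes only arise
  from CNVs surviving the strict length filter, so exactly
  `round(q × n_large)` of the length-retained gains carry focal anchors,
  `q = planted_fold × K/N`; sub-cutoff gains get Bernoulli(`q`) anchors.
  The focal fraction among gain-genes therefore equals the target by
  construction rather than only in expectation, which keeps
  planted-recovery checks from being dominated by irrelevant Monte-Carlo
  noise.
* **Case-cohort size targets the analyzable gene count.** With one gene
  per CNV, a cohort of 94 gains (≈ two-thirds surviving the length
  filter, minus control-matched removals) lands near 58 analyzable
  gain-genes — the problem size at which the enrichment statistics are
  defined. The CNV *count* of the emulated studies cannot be matched
  simultaneously under this geometry; the gene count takes precedence.
* **Controls are scaled by effect, not by count.** Uniformly placed
  control CNVs on a toy genome remove genes at a rate set by total
  control length over genome length; the defaults (1,800 gains, 900
  losses) reproduce control attrition of roughly 8% of case gain-genes
  and 4% of loss-genes. Transplanting the real control cohort's raw count
  would delete most of the toy universe.
* **The universe is the genome.** Genes without any phenotype annotation
  carry no information for any statistic in scope, so the generator does
  not model them; decoy non-1:1 orthology rows and annotations on decoy
  mice are included so loaders must exercise the exclusion rules.
* **Closure sizes are exact by partition.** Direct annotations sit only
  on leaf terms; optional second annotations are drawn within the same
  branch, so the focal and behavioural closure sizes are exact while
  closure propagation is still doing real work.
* **Expression is a latent-factor model on the log scale.** Module genes
  follow `μ + sqrt(r)·f + sqrt(1−r)·ε` with standard-normal factor and
  noise, so within-module Pearson correlation is `r` in expectation
  (equivalently `noise_sd = sqrt(1/r − 1)`); RPKM is `max(2^z − 1, 0)`,
  so `log2(RPKM + 1)` recovers the latent profile. A configurable
  fraction of background genes is silent, exercising the expression
  filter.

Not emulated: realistic chromosome lengths or gene density, linkage
structure, region/age covariates in expression, gene-length biases, or
multi-gene CNVs. Passing the synthetic checks therefore demonstrates the
statistical machinery is correct and calibrated — not that any particular
real dataset will reproduce a given effect.

## 7. Numerical choices and tie-breaking

* Strict `>` on the CNV length filter; inclusive `>=` on expression
  filter thresholds and on the `r` cutoff; `>=` ties count toward `k` in
  empirical p-values. All three follow the stated conventions of the
  emulated analyses and are asserted at their boundaries in the tests.
* Enrichment results sort by p then term id; term lists sort
  lexicographically; edge lists store pairs canonically
  (`gene_a < gene_b`) — every emitted ordering is deterministic.
* Top-fraction thresholding keeps all pairs tied at the cutoff value.
* Storey π₀ is clamped to `[1/m, 1]`; q-values are capped at 1.
* Empirical p can never be 0 (the `+1`); `k = n_perm` gives exactly 1.

## 8. Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run entirely on generated data:
hypergeometric tails are verified against combinatorial enumeration on
every instance with `N ≤ 20`; graph statistics against brute-force pair
enumeration on 200-node random graphs; null calibration of the cohesion
test with 200 uniform candidate draws × 1,000 permutations on a
2,000-gene planted-module network (compared against the uniform with a
one-sided Kolmogorov–Smirnov test — permutation p on a discrete grid is
super-uniform by construction, so only an excess of small p-values is a
failure); planted-signal recovery over 100 cohorts at the default scale
plus planted-module cohesion at 10,000 permutations. These sizes were
chosen so the whole suite completes in about a minute on a laptop while
leaving the Monte-Carlo error well inside the asserted margins.

## 9. Known limitations

* The gain rule's span containment is the most inclusive defensible
  reading of "completely overlapped"; boundary conventions of the
  original curation (e.g. CNV endpoints inside introns) may differ in
  edge cases.
* Storey's π₀ estimate is undefined when all p-values are small; the
  implementation falls back to the clamp and the small-family warning.
* The comparative composite-background test generalizes a procedure whose
  published description is partial; the set bookkeeping implemented here
  (purge target-annotated genes, deduplicate the union, draw candidate-
  sized sets) is recorded on every result object so analyses are
  auditable.
* Gene-length bias in CNV hit rates is not corrected; the assignment
  rules were chosen to mitigate it, and a length-distribution diagnostic
  is the appropriate companion analysis.
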