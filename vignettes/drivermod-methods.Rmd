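---
title: "Methods: gene ranking and module detection in co-annotation networks"
author: "drivermod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene ranking and module detection in co-annotation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drivermod)
options(drivermod.verbose = FALSE)
```

## The problem

Somatic mutation frequency alone is a noisy signal for identifying the
genes that drive a cancer: passengers in large or fragile genes mutate
often, and genuine drivers of intermediate frequency hide in the bulk of
the distribution. Because driver genes act through a limited set of
pathways, a gene's position in a functional network carries complementary
information. `drivermod` combines the two signals: mutation frequency
selects the candidate universe, shared biological-process annotation
defines a weighted network over it, network topology ranks the genes, and
a stochastic search extracts small, densely connected candidate modules.

## The network model

Nodes are V1 ∪ V2. V1 is the `top_n` (default 200) most frequently
mutated genes; duplicated symbols in the input are merged by summing
their counts, on the view that multiple records accumulate evidence.
V2 adds every annotated gene outside V1 sharing at least one biological
process with a V1 gene — one hop only, not a transitive closure, so the
network stays anchored to the mutation signal. Edges join genes sharing
≥ 1 process and carry the shared-process count as an integer weight.
Annotations are read flat; no propagation up the GO hierarchy is
performed (annotation files that are already ancestor-closed will simply
yield denser networks). GAF input is restricted to aspect "P", rows with
a NOT qualifier are dropped, and evidence codes are deliberately not
filtered — the minimal reading of "biological process annotation".

## Topological characteristics

Five per-gene features: degree; strength (sum of incident weights);
betweenness centrality; eigenvector centrality; and weight entropy
−Σ_e (w_e/s)·ln(w_e/s) over the node's incident weights (0 for degree
≤ 1), which measures how evenly a gene spreads its functional coupling.

Numerical conventions that matter:

* **Betweenness** uses weighted shortest paths with edge length 1/weight
  (stronger coupling = shorter path; the unit-length alternative is
  available via `betweenness_distance = "unit"`), normalized by
  (n−1)(n−2)/2 for n > 2.
* **Eigenvector centrality** is ill-defined on a disconnected graph, so
  it is computed on the largest connected component and set to 0
  elsewhere (with a log note). It is computed by shifted power iteration
  (A + I, fixed uniform start, tolerance 1e-13) rather than a sparse
  Lanczos solver: the shift breaks the bipartite eigenvalue tie, and the
  fixed start makes results bitwise reproducible across runs and
  platforms, which the pipeline's determinism guarantee requires. The
  vector is reported non-negative with unit L2 norm.
* **Entropy** uses the natural log; its maximum for a degree-d node is
  ln d, attained at uniform incident weights.

## Laplacian-Score ranking

The Laplacian Score of a feature f on a similarity graph S is
L_r = f̃ᵀLf̃ / f̃ᵀDf̃ with D = diag(S𝟙), L = D − S and f̃ the D-weighted
centring of f. Small L_r means f varies little across strong edges —
the feature preserves local structure. Here S is the gene network's
weighted adjacency itself: no kNN or RBF kernel is interposed, because
the network is already the similarity structure of interest.

The score rates *features*, not genes, so a second stage produces the
gene ranking: each usable feature is z-scored across genes and summed
with weight ω_r ∝ 1/(L_r + ε), ε = 1e-12, normalized to Σω_r = 1. Genes
are sorted by this composite descending, ties broken by symbol, giving a
total, reproducible order. An alternative reading — transposing the
Laplacian-Score machinery to score genes directly — is isolated behind
the same `rank_genes()` interface and could be swapped in; the composite
reading was chosen because it uses the score exactly as defined while
still yielding the per-gene priorities the pipeline needs. Constant
features are excluded with a warning (on an all-constant input, ranking
is refused); affine transforms of a feature leave its L_r unchanged, so
the ranking is scale-free.

## Module detection

Growth starts from each of the top `n_seeds` (default 50) ranked genes.
The composite score of a gene set m with |m| = k ≥ 2 is

* a density term: (Σ internal edge weights) / C(k,2), normalized by the
  network's maximum edge weight, plus
* a rank term: the mean over members of 1 − (rank−1)/(n−1),

each in [0, 1]. The formula weights both terms equally; the balance is
deliberate — density alone collapses onto the single strongest edge,
rank alone onto the top of the list. A singleton seed is scored by its
rank term alone (the density term needs a pair), so the first accepted
neighbour must contribute enough edge density to beat the seed's rank
term; this keeps weakly attached neighbours out from the first step.

Each growth step samples one candidate neighbour with probability
proportional to its total edge weight into the module — the Monte-Carlo
element — and accepts it only on strict score improvement. Growth stops
after `patience` (default 15) consecutive rejections or at `max_size`
(10) genes. Strict improvement means the trajectory's final state is
also its best state. Individual growths frequently stall early (for
example on a locally optimal pair); recovery comes from breadth:
`restarts_per_seed` (default 20) independent growths per seed, pooled
over all seeds.

Refinement then (1) deduplicates identical gene sets, (2) keeps sizes in
[`min_size`, `max_size`] = [4, 10] — small enough to be interpretable,
large enough to be non-trivial, with under-grown candidates discarded
rather than force-grown, (3) removes strict subsets of surviving
modules, and (4) greedily resolves overlaps in score order, dropping any
module whose Jaccard overlap with a retained one exceeds
`overlap_jaccard_max` (default 0.5). Subset removal precedes overlap
resolution so that a large module cannot be knocked out by its own
fragments. Ties in score are broken by the lexicographic gene-set key,
keeping refinement deterministic.

## Enrichment

For module m and pathway Pi inside an N-gene universe (by default the
constructed network's node set; the annotation universe is a documented
alternative) with K = |Pi ∩ universe|, n = |m| and overlap k, the point
probability is C(K,k)·C(N−K,n−k)/C(N,n), evaluated in log-gamma space.
Enrichment conventionally asks P(X ≥ k), so the upper tail — the sum of
point masses from k up — is the quantity tested against α = 0.05. Both
are reported per pathway. A module is significant when at least
`min_enriched` = 2 pathways pass; no multiple-testing correction is
applied across the pathway list by default (a Bonferroni switch
exists), matching the raw-threshold convention of the ≥ 2-pathway rule:
demanding two independent raw hits is itself the guard against
one-pathway flukes.

## Evaluation

Against a benchmark gene set of size N within the ranking universe:
genes are labelled positive if ranked ≤ N (top-N binarization) and
evaluated with stratified 5-fold cross-validated AUC-ROC (stratification
keeps both classes in every fold, so the per-fold AUC is defined; the
AUC is computed rank-based, identical to U/(n1·n2)); a one-sided
Mann–Whitney U test that benchmark genes hold better ranks (exact null
for groups ≤ 20, normal approximation with tie correction above); and a
one-sided Wilcoxon signed-rank test pairing the sorted benchmark ranks
under the model with the elementwise median of sorted benchmark ranks
under `n_random` seeded random permutations. The median pairing is the
minimal concrete construction of "compared to random rankings": it
yields one stable reference vector instead of an arbitrary single
permutation. Degenerate cases (single benchmark gene, all-zero
differences) return p = 1 with a warning rather than an error.

## The synthetic generator

`synthetic_spec()` defaults define the study conditions used throughout
the tests: 300 genes; 5 planted modules of 6 genes, each sharing 5
private processes (guaranteeing within-module edge weight ≥ 5); 150
background processes carried by each gene with probability 0.01; a
40-gene benchmark drawn half from planted genes; and 11 pathway sets —
two decoy-padded pathways per planted module (cancer pathways overlap
heavily, and the ≥ 2-pathway rule needs at least two coverers to be
satisfiable) plus one random filler. Background sharing at these rates
gives a mean background degree near 4.5 and background edge weights of
about 1, so the planted contrast (weight ≥ 5 cliques over a weight-1
background) mirrors the regime where functional modules are visible but
embedded in annotation noise. Every gene additionally carries one
gene-specific singleton process, so all genes are annotated (as in
curated GO) without adding edges. Mutation counts are overdispersed
negative-binomial integers, background mean 25, planted mean 120 + 30
offset, so planted genes reliably enter V1 without occupying fixed
ranks. Identical specs produce byte-identical files.

What the generator does *not* emulate: the heavy-tailed size
distribution of real GO terms, the DAG structure of the ontology,
correlated annotation noise, inter-module pathway crosstalk, and the
gene-length confounding of real mutation counts. Passing tests
therefore demonstrate the machinery is correct and well-calibrated on
planted structure, not that the biological signal in any given real
dataset is as clean.

## Problem sizes and determinism

The test suite and the acceptance script run the full pipeline at the
default 300-gene scale (seconds per run) and validate centralities and
p-values against brute-force oracles on graphs of ≤ 7 nodes and
universes of ≤ 12 genes, where exhaustive enumeration is exact. All
stochastic stages (growth, folds, permutations, generation) consume
seeds derived from a single `rng_seed`, and the package restores the
caller's RNG state after every seeded operation, so identical inputs
yield identical outputs — including byte-identical ranking and module
files across pipeline reruns.

## Known limitations

* Gene symbols are matched after uppercasing only; no alias or
  cross-reference resolution is attempted.
* The composite module score's equal term weighting is a default, not an
  optimum; both terms are exposed for sensitivity analysis.
* Strict-improvement growth cannot traverse score plateaus; on networks
  with perfectly uniform within-module weights, single growths recover
  modules only through favourable proposal orders, and detection relies
  on restarts (this is visible in the planted-recovery tests).
* The evaluation model treats the benchmark as ground truth; benchmarks
  of broadly cancer-related genes will depress measured AUC for a
  cancer-type-specific ranking, which is an interpretation caveat, not
  a defect of the statistics.
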