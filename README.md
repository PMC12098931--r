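# drivermod

Ranking candidate cancer driver genes and detecting candidate driver
modules from mutation-frequency data and shared biological-process
annotations.

`drivermod` is for computational biologists who have, for one cancer type,
(a) a table of genes with somatic mutation counts or frequencies and (b)
gene → Gene Ontology biological-process annotations, and who want a
prioritized gene list and a set of small, densely connected functional
modules — plus benchmark-based evaluation of both. Everything is testable
end to end on built-in synthetic data with planted structure, so no
external downloads are needed to validate the method.

## Method

**Network.** The node set is V1 ∪ V2: V1 is the top 200 most frequently
mutated genes; V2 adds every annotated gene that shares at least one
biological process with a V1 gene. Two genes are joined by an edge iff
they share ≥ 1 process; the edge weight is the number of shared
processes, giving an undirected weighted graph G = (V, E, W).

**Ranking.** Five topological characteristics are computed per gene:
degree, strength (sum of incident weights), weighted betweenness (edge
length 1/w), eigenvector centrality (largest component, L2-normalized)
and weight entropy (Shannon entropy of the node's normalized
incident-weight distribution). Each feature f is scored by the classical
unsupervised Laplacian Score on the gene network itself,

    L_r = (f̃ᵀ L f̃) / (f̃ᵀ D f̃),   f̃ = f − (fᵀD𝟙 / 𝟙ᵀD𝟙)𝟙,

with S the weighted adjacency, D = diag(S𝟙), L = D − S. Small L_r means
the feature respects local network structure, so genes are scored by a
z-scored feature sum with weights ∝ 1/(L_r + ε).

**Modules.** From each high-ranked seed gene, a Monte-Carlo seed-and-extend
heuristic samples neighbours with probability proportional to their edge
weight into the module and accepts an addition only if it strictly
improves a composite score (edge-density term + mean-rank term). Pooled
candidates are refined: size constrained to 4–10 genes, redundant
subsets dropped, and overlaps above Jaccard 0.5 resolved by score.

**Enrichment and evaluation.** Each module m is scored against pathway
gene sets Pi with the hypergeometric probability
C(K,k)·C(N−K,n−k)/C(N,n) (upper tail for the test), and flagged
significant when ≥ 2 pathways reach p ≤ 0.05. Rankings are evaluated
against benchmark gene sets by top-N binarization (N = benchmark size),
5-fold cross-validated AUC-ROC, a one-sided Mann–Whitney U test on
benchmark vs non-benchmark ranks, and a one-sided Wilcoxon signed-rank
test against seeded random rankings.

## Worked example

```r
library(drivermod)
options(drivermod.verbose = FALSE)

# synthetic dataset: 300 genes, 5 planted 6-gene modules, benchmark +
# pathway GMTs with known ground truth
dataset <- generate_synthetic(synthetic_spec(rng_seed = 42), "example_data")

res <- run_pipeline(list(
  mutations     = dataset$paths$mutations,
  annotations   = dataset$paths$annotations,
  benchmark_gmt = dataset$paths$benchmark,
  pathways_gmt  = dataset$paths$pathways,
  rng_seed      = 42
), "example_bundle")

head(res$ranking)
#>   gene    score rank
#> 1 G020 4.687740    1
#> 2 G013 3.403263    2
#> 3 G011 3.368934    3
#> 4 G014 2.754509    4
#> 5 G008 2.662815    5
#> 6 G010 2.638038    6
```

The top-ranked genes are planted-module members (G013–G020 span planted
modules 3 and 4), as they should be: planted genes are both frequently
mutated and densely co-annotated. The best module recovers planted
module 3 (G013–G018) in full, with the top-ranked gene G020 — a member
of the adjacent planted module that happens to share background
processes — attached:

```r
res$modules[[1]][c("genes", "seed", "composite_score", "significant")]
#> $genes
#> [1] "G013" "G014" "G015" "G016" "G017" "G018" "G020"
#> $seed            $composite_score   $significant
#> [1] "G020"       [1] 1.696986       [1] TRUE

subset(res$modules[[1]]$enrichment, p_tail <= 0.05)
#>          pathway   N  K n k      p_point       p_tail
#> 5 PW_PLANTED_03A 273 11 7 6 5.833254e-09 5.849157e-09
#> 6 PW_PLANTED_03B 273 10 7 6 2.661599e-09 2.667382e-09
```

Two pathways are enriched at p ≤ 0.05, so the module is significant
under the ≥ 2-pathway rule. Evaluation against the synthetic benchmark
(40 genes, half planted):

```r
res$evaluation$BENCH[c("fold_aucs", "mannwhitney_p", "wilcoxon_p")]
#> $fold_aucs
#> [1] 0.7535461 0.7096774 0.7285714 0.6753247 0.8122270
#> $mannwhitney_p        $wilcoxon_p
#> [1] 1.077049e-06      [1] 5.939779e-08
```

Fold AUCs around 0.68–0.81 say the ranking separates benchmark from
non-benchmark genes well but not perfectly — the benchmark is half
background genes by construction. Both rank tests reject their nulls
decisively: benchmark genes sit far higher than chance. On this run all
5 planted modules are recovered at Jaccard ≥ 0.8 among 20 retained
modules.

A thin command-line wrapper with subcommands (`simulate`,
`build-network`, `rank`, `detect-modules`, `enrich`, `evaluate`,
`run-all`, `gene-info`) is installed at
`system.file("cli/drivermod.R", package = "drivermod")`.

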