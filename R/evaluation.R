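# Benchmark-based evaluation of a gene ranking: top-N binarization,
# stratified k-fold AUC-ROC, a one-sided Mann-Whitney U test comparing the
# ranks of benchmark vs non-benchmark genes, and a one-sided Wilcoxon
# signed-rank test of the model ranking against seeded random rankings.
# All alternatives are directional: benchmark genes are expected to hold
# better (smaller-number) ranks.

#' Binarize a ranking at the benchmark's size
#'
#' With `N = |benchmark within the ranking universe|`, each gene is
#' predicted positive iff its rank is `<= N`; the truth label is benchmark
#' membership.
#'
#' @param ranking A `ranked_genes` data frame.
#' @param benchmark A `gene_set` of known positives.
#' @return List with `predicted` and `truth` (named 0/1 integer vectors
#'   over the ranking universe, in rank order) and `n_top = N`.
#' @export
binarize_top_n <- function(ranking, benchmark) {
  in_universe <- intersect(benchmark$genes, ranking$gene)
  if (length(in_universe) == 0L) {
    validation_error("benchmark '%s' has no genes in the ranking universe",
                     benchmark$name)
  }
  N <- length(in_universe)
  predicted <- as.integer(ranking$rank <= N)
  truth <- as.integer(ranking$gene %in% in_universe)
  names(predicted) <- names(truth) <- ranking$gene
  list(predicted = predicted, truth = truth, n_top = N)
}

# Rank-based AUC: probability that a random positive scores above a random
# negative (ties counted 1/2); identical to U / (n1 * n2).
rank_auc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated AUC-ROC of a ranking against a benchmark
#'
#' Genes are split into `folds` stratified folds (class balance preserved)
#' governed by `rng_seed`; per fold, the AUC is computed from the ranking
#' scores against benchmark membership restricted to that fold. A fold
#' that ends up single-class is skipped with a warning (its AUC is `NA`).
#'
#' @param ranking A `ranked_genes` data frame.
#' @param benchmark A `gene_set` of known positives.
#' @param folds Number of folds (default 5).
#' @param rng_seed Integer seed for the fold assignment.
#' @return Numeric vector of `folds` AUC values in `[0, 1]`.
#' @export
auc_cv <- function(ranking, benchmark, folds = 5, rng_seed = 1) {
  if (folds < 2) config_error("folds must be >= 2")
  b <- binarize_top_n(ranking, benchmark)
  truth <- b$truth
  scores <- ranking$score
  fold_id <- integer(length(truth))
  with_rng_seed(rng_seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(truth == cls)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  aucs <- vapply(seq_len(folds), function(f) {
    sel <- fold_id == f
    a <- rank_auc(scores[sel], truth[sel])
    if (is.na(a)) warning(sprintf("fold %d has a single class; skipped", f))
    a
  }, 0)
  aucs
}

#' One-sided Mann-Whitney U test on benchmark vs non-benchmark ranks
#'
#' Tests whether benchmark genes hold better (smaller-number) ranks than
#' non-benchmark genes within the ranked list. The exact null distribution
#' is used when both groups have at most 20 genes; otherwise the normal
#' approximation with tie correction.
#'
#' @param ranking A `ranked_genes` data frame.
#' @param benchmark A `gene_set`.
#' @return List with elements `U` (the Mann-Whitney statistic for the
#'   benchmark group) and `p` (one-sided p-value).
#' @export
mann_whitney_ranks <- function(ranking, benchmark) {
  is_bench <- ranking$gene %in% benchmark$genes
  x <- ranking$rank[is_bench]
  y <- ranking$rank[!is_bench]
  if (length(x) == 0L || length(y) == 0L) {
    validation_error("both benchmark and non-benchmark groups must be non-empty")
  }
  exact <- length(x) <= 20L && length(y) <= 20L
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = "less", exact = exact, correct = TRUE)
  )
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' One-sided Wilcoxon signed-rank test against random rankings
#'
#' Pairs the sorted benchmark-gene ranks under the model with the
#' elementwise median of sorted benchmark-gene ranks under `n_random`
#' seeded random permutations of the universe, and tests whether the model
#' ranks are better (smaller). Degenerate inputs (a single benchmark gene,
#' or all paired differences zero) return `p = 1` with a warning.
#'
#' @param ranking A `ranked_genes` data frame.
#' @param benchmark A `gene_set`.
#' @param n_random Number of random permutations (default 99).
#' @param rng_seed Integer seed for the permutations.
#' @return One-sided p-value.
#' @export
wilcoxon_vs_random <- function(ranking, benchmark, n_random = 99,
                               rng_seed = 1) {
  if (n_random < 1) config_error("n_random must be >= 1")
  n <- nrow(ranking)
  model_ranks <- sort(ranking$rank[ranking$gene %in% benchmark$genes])
  m <- length(model_ranks)
  if (m == 0L) {
    validation_error("benchmark '%s' has no genes in the ranking universe",
                     benchmark$name)
  }
  if (m == 1L) {
    warning("single benchmark gene: signed-rank test degenerate; p = 1")
    return(1)
  }
  rand <- with_rng_seed(rng_seed, {
    vapply(seq_len(n_random), function(i) sort(sample.int(n, m)), numeric(m))
  })
  rand_ranks <- apply(rand, 1L, median)
  d <- model_ranks - rand_ranks
  if (all(d == 0)) {
    warning("model and random reference ranks identical; p = 1")
    return(1)
  }
  ht <- suppressWarnings(
    wilcox.test(model_ranks, rand_ranks, paired = TRUE,
                alternative = "less", exact = FALSE, correct = TRUE)
  )
  ht$p.value
}

#' Full evaluation report for one benchmark
#'
#' Convenience wrapper combining [auc_cv()], [mann_whitney_ranks()] and
#' [wilcoxon_vs_random()].
#'
#' @inheritParams auc_cv
#' @inheritParams wilcoxon_vs_random
#' @return A list of class `evaluation_report` with fields
#'   `benchmark_name`, `fold_aucs`, `mannwhitney_u`, `mannwhitney_p`,
#'   `wilcoxon_p`, `n_benchmark_in_universe`.
#' @export
evaluate_ranking <- function(ranking, benchmark, folds = 5, n_random = 99,
                             rng_seed = 1) {
  aucs <- auc_cv(ranking, benchmark, folds = folds, rng_seed = rng_seed)
  mw <- mann_whitney_ranks(ranking, benchmark)
  wp <- wilcoxon_vs_random(ranking, benchmark, n_random = n_random,
                           rng_seed = rng_seed)
  structure(list(
    benchmark_name = benchmark$name,
    fold_aucs = aucs,
    mannwhitney_u = mw$U,
    mannwhitney_p = mw$p,
    wilcoxon_p = wp,
    n_benchmark_in_universe = length(intersect(benchmark$genes, ranking$gene))
  ), class = "evaluation_report")
}
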