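# Hypergeometric pathway enrichment. For a module of n genes drawn from an
# N-gene universe containing K pathway genes, the point probability of
# observing exactly k shared genes is C(K,k) C(N-K,n-k) / C(N,n); the
# upper tail P(X >= k) is used for the significance rule (a module is
# significant when at least `min_enriched` pathways reach p <= alpha).

check_hyper_args <- function(N, K, n, k) {
  for (v in list(N = N, K = K, n = n, k = k)) {
    if (length(v) != 1L || is.na(v) || v < 0 || v != floor(v)) {
      domain_error("N, K, n, k must be single non-negative integers")
    }
  }
  if (K > N) domain_error("constraint violated: K <= N (K=%d, N=%d)", K, N)
  if (n > N) domain_error("constraint violated: n <= N (n=%d, N=%d)", n, N)
  if (k > n) domain_error("constraint violated: k <= n (k=%d, n=%d)", k, n)
  if (k > K) domain_error("constraint violated: k <= K (k=%d, K=%d)", k, K)
  if (n - k > N - K) {
    domain_error("constraint violated: n - k <= N - K (n-k=%d, N-K=%d)",
                 n - k, N - K)
  }
  invisible(NULL)
}

#' Hypergeometric point probability
#'
#' Exact probability `C(K,k) C(N-K,n-k) / C(N,n)` of drawing exactly `k`
#' pathway genes in a module of `n` genes from an `N`-gene universe with
#' `K` pathway genes. Evaluated in log-gamma space for numerical range.
#'
#' @param N Universe size. @param K Pathway genes in the universe.
#' @param n Module size. @param k Overlap count.
#' @return Probability in `[0, 1]`.
#' @export
hypergeometric_point <- function(N, K, n, k) {
  check_hyper_args(N, K, n, k)
  exp(lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n))
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)`: the sum of [hypergeometric_point()] over
#' `j = k, ..., min(n, K)`.
#'
#' @inheritParams hypergeometric_point
#' @return Probability in `[0, 1]` (1 when `k = 0`).
#' @export
hypergeometric_tail <- function(N, K, n, k) {
  check_hyper_args(N, K, n, k)
  j <- k:min(n, K)
  if (k > min(n, K)) return(0)
  min(1, sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n))))
}

#' Score a module against pathway gene sets
#'
#' Computes one enrichment result per pathway: the universe size `N`, the
#' pathway size within the universe `K`, the module size `n`, the overlap
#' `k`, and the point and upper-tail hypergeometric probabilities. The
#' module is flagged significant when at least `min_enriched` pathways
#' reach `p_tail <= alpha`.
#'
#' @param module A `gene_module` whose genes are all in `universe`.
#' @param pathways List of `gene_set` objects (intersected with the
#'   universe before `K` is counted).
#' @param universe Character vector of all genes in the dataset (the
#'   constructed network's nodes by default in the pipeline).
#' @param alpha Per-pathway significance threshold (default 0.05).
#' @param min_enriched Minimum number of enriched pathways for overall
#'   significance (default 2).
#' @param bonferroni If `TRUE`, `alpha` is divided by the number of
#'   pathways before thresholding (off by default; the rule of record is
#'   the raw threshold).
#' @return The module with `enrichment` (a data frame with columns
#'   `pathway`, `N`, `K`, `n`, `k`, `p_point`, `p_tail`) and `significant`
#'   filled in.
#' @export
evaluate_module <- function(module, pathways, universe, alpha = 0.05,
                            min_enriched = 2, bonferroni = FALSE) {
  universe <- unique(norm_symbol(universe))
  if (length(universe) == 0L) validation_error("empty gene universe")
  if (!all(module$genes %in% universe)) {
    validation_error("module genes outside the universe: %s",
                     paste(setdiff(module$genes, universe), collapse = ", "))
  }
  N <- length(universe)
  n <- length(module$genes)
  res <- lapply(pathways, function(pw) {
    pw_genes <- intersect(pw$genes, universe)
    K <- length(pw_genes)
    k <- length(intersect(module$genes, pw_genes))
    data.frame(pathway = pw$name, N = N, K = K, n = n, k = k,
               p_point = hypergeometric_point(N, K, n, k),
               p_tail = hypergeometric_tail(N, K, n, k),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  thr <- if (bonferroni) alpha / max(1L, nrow(res)) else alpha
  module$enrichment <- res
  module$significant <- sum(res$p_tail <= thr) >= min_enriched
  module
}
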