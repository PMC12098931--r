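# Independent brute-force oracles used to validate the package's
# implementations. These deliberately avoid the code paths they check.

options(drivermod.verbose = FALSE)

# Brute-force betweenness centrality from exhaustive simple-path
# enumeration. W is a symmetric weight matrix; edge length = 1/weight.
# Paths of equal length are detected with an exact comparison, which is
# why oracle graphs draw weights from powers of two: 1/w and their sums
# are then exact in binary floating point.
oracle_betweenness <- function(W, normalized = TRUE) {
  n <- nrow(W)
  btw <- numeric(n)
  all_paths <- function(from, to, visited) {
    if (from == to) return(list(to))
    out <- list()
    for (nxt in which(W[from, ] > 0)) {
      if (!nxt %in% visited) {
        for (p in all_paths(nxt, to, c(visited, nxt))) {
          out[[length(out) + 1L]] <- c(from, p)
        }
      }
    }
    out
  }
  path_len <- function(p) {
    sum(vapply(seq_len(length(p) - 1L),
               function(i) 1 / W[p[i], p[i + 1L]], 0))
  }
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      paths <- all_paths(s, t, s)
      if (length(paths) == 0L) next
      lens <- vapply(paths, path_len, 0)
      shortest <- paths[lens == min(lens)]
      for (p in shortest) {
        inner <- setdiff(p, c(s, t))
        btw[inner] <- btw[inner] + 1 / length(shortest)
      }
    }
  }
  if (normalized && n > 2L) btw <- btw / ((n - 1) * (n - 2) / 2)
  btw
}

# Dense eigen-decomposition oracle for eigenvector centrality
# (non-negative principal eigenvector, L2-normalized).
oracle_eigen_centrality <- function(W) {
  ev <- eigen(W, symmetric = TRUE)$vectors[, 1L]
  ev <- abs(ev)
  ev / sqrt(sum(ev^2))
}

# Exhaustive draw-counting oracle for the hypergeometric distribution:
# enumerate every size-n subset of an N-gene universe whose first K
# elements are the pathway, and count overlaps.
oracle_hyper <- function(N, K, n) {
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)
  counts <- tabulate(overlap + 1L, nbins = n + 1L)
  counts / ncol(draws)  # index j+1 = P(X = j)
}

# Trapezoidal ROC-integration oracle for the AUC.
oracle_auc_trapezoid <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  labels <- labels[ord]
  scores <- scores[ord]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  # walk unique thresholds, accumulating TPR/FPR points
  tpr <- c(0); fpr <- c(0)
  i <- 1L
  tp <- 0L; fp <- 0L
  while (i <= length(labels)) {
    j <- i
    while (j <= length(labels) && scores[j] == scores[i]) j <- j + 1L
    tp <- tp + sum(labels[i:(j - 1L)] == 1)
    fp <- fp + sum(labels[i:(j - 1L)] == 0)
    tpr <- c(tpr, tp / n1); fpr <- c(fpr, fp / n0)
    i <- j
  }
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

# Exact one-sided Mann-Whitney p-value by exhaustive enumeration of all
# C(n1+n2, n1) group assignments of the pooled ranks.
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2L, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  mean(u_all <= u_obs)
}

# Random connected weighted igraph with weights from {1, 2, 4, 8} (see
# oracle_betweenness for why powers of two).
random_weighted_graph <- function(n, p_edge = 0.5, connected = TRUE) {
  repeat {
    W <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (stats::runif(1) < p_edge) {
          W[i, j] <- W[j, i] <- sample(c(1, 2, 4, 8), 1L)
        }
      }
    }
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
    igraph::V(g)$name <- sprintf("G%02d", seq_len(n))
    if (!connected || igraph::is_connected(g)) return(list(graph = g, W = W))
  }
}
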