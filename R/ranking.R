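# Laplacian-Score gene ranking. The classical unsupervised Laplacian Score
# (He & Niyogi) rates each topological feature by how well it preserves the
# local structure of the gene network itself (small score = the feature
# varies smoothly along strong edges). Genes are then scored by an
# inverse-score-weighted sum of z-scored features, so locality-preserving
# features dominate the composite ranking.

#' Laplacian Score of each topological feature
#'
#' Uses the weighted adjacency of the gene network as the similarity matrix
#' S, with D the diagonal row-sum matrix and L = D - S. Each feature column
#' f is centred to f-tilde = f - (f'D1 / 1'D1) 1 and scored as
#' L_r = (f-tilde' L f-tilde) / (f-tilde' D f-tilde). Features with zero
#' variance (or zero degree-weighted variance) are excluded with a warning.
#'
#' @param features A `topology_features` data frame.
#' @param network The `igraph` network the features were computed on.
#' @return Named numeric vector of Laplacian scores (all >= 0), one per
#'   usable feature.
#' @export
laplacian_feature_scores <- function(features, network) {
  n <- igraph::vcount(network)
  if (n < 2L) validation_error("Laplacian scoring needs at least 2 nodes")
  if (igraph::ecount(network) == 0L) {
    validation_error("Laplacian scoring needs at least one edge")
  }
  stopifnot(identical(features$gene, igraph::V(network)$name))
  S <- igraph::as_adjacency_matrix(network, attr = "weight", sparse = TRUE)
  S <- methods::as(S, "generalMatrix")
  d <- Matrix::rowSums(S)
  feat_cols <- setdiff(names(features), "gene")
  scores <- numeric(0)
  for (fc in feat_cols) {
    f <- features[[fc]]
    if (var(f) == 0) {
      warning(sprintf("feature '%s' is constant; excluded from ranking", fc))
      next
    }
    ft <- f - sum(f * d) / sum(d)
    den <- sum(d * ft^2)
    if (den <= 0) {
      warning(sprintf(
        "feature '%s' has zero degree-weighted variance; excluded", fc))
      next
    }
    num <- sum(ft * (d * ft - as.numeric(S %*% ft)))  # f'Lf
    scores[[fc]] <- max(0, num / den)
  }
  if (length(scores) == 0L) {
    validation_error("all features constant; ranking impossible")
  }
  scores
}

#' Rank genes by an inverse-Laplacian-Score-weighted feature composite
#'
#' Each usable feature is z-scored across genes; feature r receives weight
#' proportional to 1/(L_r + eps) (eps = 1e-12), normalized to sum to one,
#' so features with better locality preservation (small Laplacian score)
#' contribute more. Genes are sorted by composite score descending, ties
#' broken by symbol ascending; ranks are 1-based with no gaps.
#'
#' @param features A `topology_features` data frame.
#' @param feature_ls Named Laplacian scores from
#'   [laplacian_feature_scores()].
#' @param network The `igraph` network (used for the node universe check).
#' @return A `data.frame` of class `ranked_genes` with columns `gene`,
#'   `score`, `rank`, carrying attributes `feature_ls` and
#'   `feature_weights`.
#' @export
rank_genes <- function(features, feature_ls, network) {
  if (length(feature_ls) == 0L) {
    validation_error("no usable features to rank on")
  }
  stopifnot(all(names(feature_ls) %in% names(features)))
  eps <- 1e-12
  wts <- 1 / (feature_ls + eps)
  wts <- wts / sum(wts)
  Z <- vapply(names(wts), function(fc) {
    f <- features[[fc]]
    (f - mean(f)) / sd(f)
  }, numeric(nrow(features)))
  score <- as.numeric(Z %*% wts)
  ord <- order(-score, features$gene)
  out <- data.frame(gene = features$gene[ord], score = score[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "feature_ls") <- feature_ls
  attr(out, "feature_weights") <- wts
  class(out) <- c("ranked_genes", "data.frame")
  out
}

#' Take the top n genes of a ranking as a gene set
#'
#' @param ranking A `ranked_genes` data frame.
#' @param n Number of genes, `1 <= n <= nrow(ranking)`.
#' @return A `gene_set` named `"topN"` with the genes of rank <= n.
#' @export
top_n_genes <- function(ranking, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n > nrow(ranking)) {
    config_error("n must be between 1 and %d", nrow(ranking))
  }
  gene_set("topN", ranking$gene[seq_len(as.integer(n))])
}
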