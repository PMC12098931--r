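# Network construction: node selection (top-frequency genes V1 plus their
# one-hop biological-process neighbourhood V2), shared-process edges with
# integer weights, and the five per-node topological characteristics.

#' Select network nodes from mutation records and annotations
#'
#' V1 is the top `top_n` most frequently mutated genes; V2 adds every
#' annotated gene outside V1 that shares at least one biological process
#' with some V1 gene (one hop, no transitive closure).
#'
#' @param records A `mutation_table` as returned by [load_mutation_table()]
#'   (sorted by mutation count descending).
#' @param annotations An `annotation_map` from [load_annotations()].
#' @param top_n Number of top-frequency genes forming V1 (default 200).
#' @return A list of class `node_selection` with `v1` (ordered character
#'   vector), `v2` (character vector, disjoint from `v1`) and `all_nodes`.
#' @export
select_nodes <- function(records, annotations, top_n = 200) {
  if (!is.numeric(top_n) || length(top_n) != 1L || top_n < 1) {
    config_error("top_n must be a positive integer (got %s)",
                 deparse(substitute(top_n)))
  }
  top_n <- as.integer(top_n)
  v1 <- head(records$gene, min(top_n, nrow(records)))
  g2p <- annotations$gene_to_processes
  p2g <- annotations$process_to_genes
  v1_proc <- unique(unlist(g2p[intersect(v1, names(g2p))], use.names = FALSE))
  v2 <- character(0)
  if (length(v1_proc) > 0L) {
    v2 <- setdiff(unique(unlist(p2g[v1_proc], use.names = FALSE)), v1)
    v2 <- sort(v2)
  }
  dm_log("node selection: |V1| = %d, |V2| = %d", length(v1), length(v2))
  structure(list(v1 = v1, v2 = v2, all_nodes = c(v1, v2)),
            class = "node_selection")
}

#' Build the weighted gene co-annotation network
#'
#' Creates an undirected graph over the selected nodes with an edge between
#' every pair of genes sharing at least one biological process; the edge
#' weight is the number of shared processes. Nodes with no shared process
#' are retained as isolated vertices.
#'
#' @param selection A `node_selection` from [select_nodes()].
#' @param annotations An `annotation_map`.
#' @return An `igraph` undirected graph with vertex attribute `name` and
#'   integer edge attribute `weight` (>= 1).
#' @export
build_network <- function(selection, annotations) {
  genes <- selection$all_nodes
  if (length(genes) == 0L) validation_error("node selection is empty")
  g2p <- annotations$gene_to_processes
  pairs <- lapply(intersect(genes, names(g2p)), function(g) {
    data.frame(gene = g, process = g2p[[g]], stringsAsFactors = FALSE)
  })
  if (length(pairs) == 0L) {
    dm_log("no annotated genes among selected nodes: edgeless network")
    return(igraph::make_empty_graph(n = length(genes), directed = FALSE) |>
             igraph::set_vertex_attr("name", value = genes))
  }
  pr <- do.call(rbind, pairs)
  gi <- match(pr$gene, genes)
  procs <- sort(unique(pr$process))
  pi <- match(pr$process, procs)
  inc <- Matrix::sparseMatrix(i = gi, j = pi, x = 1,
                              dims = c(length(genes), length(procs)))
  shared <- Matrix::tcrossprod(inc)  # shared-process counts per gene pair
  shared <- methods::as(shared, "TsparseMatrix")
  keep <- shared@i < shared@j  # upper triangle, excludes self-loops
  ei <- shared@i[keep] + 1L
  ej <- shared@j[keep] + 1L
  w <- shared@x[keep]
  g <- igraph::make_empty_graph(n = length(genes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = genes)
  if (length(ei) > 0L) {
    g <- igraph::add_edges(g, rbind(ei, ej))
    g <- igraph::set_edge_attr(g, "weight", value = as.integer(w))
  } else {
    dm_log("network has no edges")
  }
  dm_log("network: %d nodes, %d edges", igraph::vcount(g), igraph::ecount(g))
  g
}

# Principal (Perron) eigenvector of a non-negative symmetric weight matrix
# by shifted power iteration with a fixed starting vector, so the result
# is fully deterministic across runs and platforms. The +I shift breaks
# the eigenvalue tie on bipartite graphs without changing eigenvectors.
principal_eigenvector <- function(A, tol = 1e-13, max_iter = 100000L) {
  n <- nrow(A)
  v <- rep(1 / sqrt(n), n)
  shift <- 1
  for (i in seq_len(max_iter)) {
    v_new <- as.numeric(A %*% v) + shift * v
    v_new <- v_new / sqrt(sum(v_new^2))
    if (max(abs(v_new - v)) < tol) {
      v <- v_new
      break
    }
    v <- v_new
  }
  v <- abs(v)
  v / sqrt(sum(v^2))
}

#' Compute per-gene topological characteristics
#'
#' For every node: degree; strength (sum of incident edge weights);
#' betweenness centrality on weighted shortest paths (edge length =
#' 1/weight by default, so stronger coupling means shorter paths),
#' normalized by (n-1)(n-2)/2 for n > 2; eigenvector centrality of the
#' weighted adjacency, computed on the largest connected component
#' (L2-normalized, non-negative; zero elsewhere); and the Shannon entropy
#' (natural log) of the node's normalized incident-weight distribution
#' (zero for degree <= 1).
#'
#' @param network An `igraph` network from [build_network()].
#' @param betweenness_distance `"inverse_weight"` (default) or `"unit"`.
#' @return A `data.frame` of class `topology_features` with columns `gene`,
#'   `degree`, `strength`, `betweenness`, `eigenvector`, `entropy`.
#' @export
compute_topology_features <- function(network,
                                      betweenness_distance =
                                        c("inverse_weight", "unit")) {
  betweenness_distance <- match.arg(betweenness_distance)
  n <- igraph::vcount(network)
  if (n < 1L) validation_error("network has no nodes")
  genes <- igraph::V(network)$name
  has_edges <- igraph::ecount(network) > 0L
  w <- if (has_edges) igraph::E(network)$weight else numeric(0)

  deg <- igraph::degree(network)
  strength <- if (has_edges) igraph::strength(network, weights = w) else
    rep(0, n)

  btw <- rep(0, n)
  if (has_edges && n > 2L) {
    dist_w <- if (betweenness_distance == "inverse_weight") 1 / w else
      rep(1, length(w))
    btw <- igraph::betweenness(network, weights = dist_w, directed = FALSE)
    btw <- btw / ((n - 1) * (n - 2) / 2)
  }

  eig <- rep(0, n)
  if (has_edges) {
    comp <- igraph::components(network)
    big <- which.max(comp$csize)
    members <- which(comp$membership == big)
    if (length(members) > 1L) {
      sub <- igraph::induced_subgraph(network, members)
      A <- as.matrix(igraph::as_adjacency_matrix(sub, attr = "weight",
                                                 sparse = TRUE))
      eig[members] <- principal_eigenvector(A)
    }
    if (comp$no > 1L) {
      dm_log("eigenvector centrality on largest component (%d of %d nodes)",
             length(members), n)
    }
  }

  ent <- rep(0, n)
  if (has_edges) {
    el <- igraph::as_edgelist(network, names = FALSE)
    inc_w <- split(c(w, w), c(el[, 1], el[, 2]))
    idx <- as.integer(names(inc_w))
    ent[idx] <- vapply(inc_w, function(wv) {
      if (length(wv) <= 1L) return(0)
      p <- wv / sum(wv)
      -sum(p * log(p))
    }, 0)
  }

  out <- data.frame(gene = genes, degree = as.numeric(deg),
                    strength = as.numeric(strength), betweenness = btw,
                    eigenvector = eig, entropy = ent,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("topology_features", "data.frame")
  out
}
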