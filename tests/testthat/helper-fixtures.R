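# Small in-code fixtures shared across test files.

# Write a two-column annotation file from a data.frame of (gene, process).
write_ann_file <- function(pairs, path = tempfile(fileext = ".tsv")) {
  writeLines(sprintf("%s\t%s", pairs$gene, pairs$process), path)
  path
}

# Build an annotation_map directly from pairs (internal constructor).
make_annmap <- function(pairs) {
  drivermod:::annotation_map(pairs$gene, pairs$process)
}

# Write a mutation table file.
write_mut_file <- function(genes, counts, path = tempfile(fileext = ".tsv")) {
  writeLines(c("gene\tcount", sprintf("%s\t%s", genes, counts)), path)
  path
}

# A mutation_table data.frame without touching files.
make_records <- function(genes, counts) {
  out <- data.frame(gene = genes, mutation_count = counts,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mutation_count, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mutation_table", "data.frame")
  out
}

# A ranked_genes data.frame with the given gene order (rank 1 first).
make_ranking <- function(genes, scores = rev(seq_along(genes))) {
  out <- data.frame(gene = genes, score = scores,
                    rank = seq_along(genes), stringsAsFactors = FALSE)
  class(out) <- c("ranked_genes", "data.frame")
  out
}

# igraph network from an edge data.frame (gene1, gene2, weight), keeping
# any extra isolated vertices listed in `nodes`.
make_network <- function(edges, nodes = NULL) {
  nodes <- unique(c(nodes, edges$gene1, edges$gene2))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, rbind(match(edges$gene1, nodes),
                                    match(edges$gene2, nodes)))
    g <- igraph::set_edge_attr(g, "weight", value = edges$weight)
  }
  g
}

# A bare gene_module for refinement tests.
make_module <- function(genes, score, seed = genes[[1]]) {
  structure(list(genes = sort(genes), seed = seed, composite_score = score,
                 enrichment = NULL, significant = NA),
            class = "gene_module")
}
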