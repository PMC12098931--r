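# Node selection, shared-process edge construction, topology features.

test_that("select_nodes caps V1 at top_n and expands V2 one hop", {
  records <- make_records(sprintf("G%03d", 1:500), 500:1)
  pairs <- data.frame(gene = c("G001", "G400", "G450"),
                      process = c("p1", "p1", "p9"))
  sel <- select_nodes(records, make_annmap(pairs), top_n = 200)
  expect_length(sel$v1, 200L)
  expect_equal(sel$v2, "G400")       # shares p1 with the V1 gene G001
  expect_false("G450" %in% sel$all_nodes)  # p9 touches no V1 gene
  expect_length(intersect(sel$v1, sel$v2), 0L)
  expect_error(select_nodes(records, make_annmap(pairs), top_n = 0),
               class = "drivermod_config_error")
})

test_that("select_nodes with empty-overlap annotations yields V2 = empty", {
  records <- make_records(c("A", "B"), c(5, 3))
  pairs <- data.frame(gene = "Z", process = "p1")  # no process touches V1
  sel <- select_nodes(records, make_annmap(pairs), top_n = 10)
  expect_equal(sel$v2, character(0))
  expect_equal(sel$all_nodes, c("A", "B"))
})

test_that("edge weights equal shared-process counts", {
  pairs <- data.frame(
    gene = c("U", "U", "V", "V", "X", "X", "X", "Y", "Y", "Y"),
    process = c("p1", "p2", "p2", "p3", "p1", "p2", "p3", "p1", "p2", "p3"))
  records <- make_records(c("U", "V", "X", "Y"), c(4, 3, 2, 1))
  map <- make_annmap(pairs)
  net <- build_network(select_nodes(records, map, top_n = 4), map)
  w_uv <- igraph::E(net)$weight[igraph::get_edge_ids(net, c("U", "V"))]
  w_xy <- igraph::E(net)$weight[igraph::get_edge_ids(net, c("X", "Y"))]
  expect_equal(w_uv, 1L)  # {p1,p2} vs {p2,p3}
  expect_equal(w_xy, 3L)  # identical {p1,p2,p3}
})

test_that("total edge weight equals per-process pair enumeration", {
  set.seed(11)
  for (rep in 1:5) {
    genes <- sprintf("G%02d", 1:25)
    pairs <- expand.grid(gene = genes, process = sprintf("P%02d", 1:12),
                         stringsAsFactors = FALSE)
    pairs <- pairs[stats::runif(nrow(pairs)) < 0.25, ]
    map <- make_annmap(pairs)
    records <- make_records(genes, 25:1)
    net <- build_network(select_nodes(records, map, top_n = 25), map)
    # oracle: per process, every gene pair contributes exactly 1
    per_process <- vapply(map$process_to_genes, function(g)
      choose(length(intersect(g, genes)), 2), 0)
    expect_equal(sum(igraph::E(net)$weight), sum(per_process))
    # handshake identity
    expect_equal(sum(igraph::strength(net)), 2 * sum(igraph::E(net)$weight))
  }
})

test_that("edge weights are invariant under gene relabeling", {
  set.seed(5)
  genes <- sprintf("G%02d", 1:12)
  pairs <- expand.grid(gene = genes, process = sprintf("P%d", 1:6),
                       stringsAsFactors = FALSE)
  pairs <- pairs[stats::runif(nrow(pairs)) < 0.4, ]
  perm <- setNames(sample(sprintf("H%02d", 1:12)), genes)
  map1 <- make_annmap(pairs)
  map2 <- make_annmap(transform(pairs, gene = perm[gene]))
  net1 <- build_network(
    select_nodes(make_records(genes, 12:1), map1, top_n = 12), map1)
  net2 <- build_network(
    select_nodes(make_records(unname(perm[genes]), 12:1), map2, top_n = 12),
    map2)
  expect_equal(sort(igraph::E(net1)$weight), sort(igraph::E(net2)$weight))
  expect_equal(igraph::ecount(net1), igraph::ecount(net2))
})

test_that("adding a shared process raises exactly one edge weight by 1", {
  pairs <- data.frame(gene = c("A", "B", "A", "C"),
                      process = c("p1", "p1", "p2", "p2"))
  records <- make_records(c("A", "B", "C"), 3:1)
  map1 <- make_annmap(pairs)
  net1 <- build_network(select_nodes(records, map1, top_n = 3), map1)
  map2 <- make_annmap(rbind(pairs, data.frame(gene = c("A", "B"),
                                              process = c("p3", "p3"))))
  net2 <- build_network(select_nodes(records, map2, top_n = 3), map2)
  w1 <- igraph::as_data_frame(net1)
  w2 <- igraph::as_data_frame(net2)
  key <- function(df) paste(pmin(df$from, df$to), pmax(df$from, df$to))
  w1$key <- key(w1); w2$key <- key(w2)
  merged <- merge(w1, w2, by = "key")
  delta <- merged$weight.y - merged$weight.x
  expect_equal(sum(delta), 1L)
  expect_equal(delta[merged$key == "A B"], 1L)
})

test_that("star-graph betweenness and uniform-weight entropy match theory", {
  edges <- data.frame(gene1 = "HUB", gene2 = c("L1", "L2", "L3", "L4"),
                      weight = 2)
  net <- make_network(edges)
  ft <- compute_topology_features(net)
  expect_equal(ft$betweenness[ft$gene == "HUB"], 1.0)
  expect_equal(ft$betweenness[ft$gene != "HUB"], rep(0, 4))
  expect_equal(ft$entropy[ft$gene == "HUB"], log(4))
  expect_equal(ft$entropy[ft$gene != "HUB"], rep(0, 4))
  expect_equal(ft$degree[ft$gene == "HUB"], 4)
  expect_equal(ft$strength[ft$gene == "HUB"], 8)
})

test_that("centralities match brute-force oracles on small weighted graphs", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(3:7, 1)
    gr <- random_weighted_graph(n)
    ft <- compute_topology_features(gr$graph)
    expect_equal(ft$betweenness, oracle_betweenness(gr$W), tolerance = 1e-10)
    expect_equal(ft$eigenvector, oracle_eigen_centrality(gr$W),
                 tolerance = 1e-8)
    expect_equal(ft$degree, rowSums(gr$W > 0))
    expect_equal(ft$strength, rowSums(gr$W))
  }
})

test_that("feature invariants hold: entropy bounds, eigenvector norm", {
  set.seed(31)
  gr <- random_weighted_graph(7, p_edge = 0.6)
  ft <- compute_topology_features(gr$graph)
  expect_true(all(ft$entropy >= 0))
  expect_true(all(ft$entropy <= log(pmax(ft$degree, 1)) + 1e-12))
  expect_equal(sum(ft$eigenvector^2), 1, tolerance = 1e-9)
  expect_true(all(ft$eigenvector >= 0))
})

test_that("disconnected networks: eigenvector zero off the largest component", {
  edges <- data.frame(gene1 = c("A", "B", "C", "X"),
                      gene2 = c("B", "C", "A", "Y"),
                      weight = c(1, 1, 1, 5))
  net <- make_network(edges, nodes = c("A", "B", "C", "X", "Y", "ISO"))
  ft <- compute_topology_features(net)
  expect_equal(ft$eigenvector[ft$gene %in% c("X", "Y", "ISO")], rep(0, 3))
  tri <- ft$eigenvector[ft$gene %in% c("A", "B", "C")]
  expect_equal(sum(tri^2), 1, tolerance = 1e-9)
  expect_equal(ft$degree[ft$gene == "ISO"], 0)
  expect_equal(ft$entropy[ft$gene == "ISO"], 0)
})

test_that("single-node network gets all-zero features", {
  net <- make_network(data.frame(gene1 = character(0),
                                 gene2 = character(0),
                                 weight = numeric(0)), nodes = "ONLY")
  ft <- compute_topology_features(net)
  expect_equal(unlist(ft[1, -1]), c(degree = 0, strength = 0,
                                    betweenness = 0, eigenvector = 0,
                                    entropy = 0))
})

test_that("feature computation is deterministic across runs", {
  set.seed(3)
  gr <- random_weighted_graph(7, p_edge = 0.6)
  expect_identical(compute_topology_features(gr$graph),
                   compute_topology_features(gr$graph))
})
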