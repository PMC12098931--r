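# Composite module scoring, Monte-Carlo growth, refinement filters.

# A network with one dominant 6-clique over a weak background ring, plus
# a ranking that favors the clique genes. Within the clique, edges
# incident to C1 carry weight 4 and the rest weight 8 (C1 shares fewer
# processes with its partners than the partners share among themselves),
# so growth from C1 climbs a density gradient: mean internal weight rises
# monotonically as the clique fills, whatever the order of additions.
clique_fixture <- function(w_seed = 4, w_core = 8) {
  clique <- sprintf("C%d", 1:6)
  bg <- sprintf("B%02d", 1:54)
  pairs <- t(utils::combn(clique, 2))
  w <- ifelse(pairs[, 1] == "C1" | pairs[, 2] == "C1", w_seed, w_core)
  edges <- rbind(
    data.frame(gene1 = pairs[, 1], gene2 = pairs[, 2], weight = w),
    data.frame(gene1 = bg, gene2 = bg[c(2:54, 1)], weight = 1),
    data.frame(gene1 = clique, gene2 = bg[1:6], weight = 1))
  net <- make_network(edges)
  ranking <- make_ranking(c(clique, bg))
  list(net = net, ranking = ranking, clique = clique)
}

test_that("composite score matches an independent formula evaluation", {
  set.seed(77)
  gr <- random_weighted_graph(15, p_edge = 0.5)
  ranking <- make_ranking(sample(igraph::V(gr$graph)$name))
  max_w <- max(gr$W)
  n <- nrow(ranking)
  for (rep in 1:200) {
    genes <- sample(ranking$gene, 5)
    got <- composite_score(genes, gr$graph, ranking)
    idx <- match(genes, igraph::V(gr$graph)$name)
    density <- sum(gr$W[idx, idx]) / 2 / (choose(5, 2) * max_w)
    ranks <- ranking$rank[match(genes, ranking$gene)]
    expected <- density + mean(1 - (ranks - 1) / (n - 1))
    expect_equal(as.numeric(got), expected, tolerance = 1e-12)
  }
})

test_that("composite score handles degenerate gene sets", {
  net <- make_network(data.frame(gene1 = "A", gene2 = "B", weight = 2),
                      nodes = c("A", "B", "C", "D"))
  ranking <- make_ranking(c("A", "B", "C", "D"))
  expect_error(composite_score("A", net, ranking),
               class = "drivermod_validation_error")
  s <- composite_score(c("C", "D"), net, ranking)  # edgeless pair
  expect_equal(as.numeric(s), mean(1 - (c(3, 4) - 1) / 3))
  expect_false(attr(s, "connected"))
  s2 <- composite_score(c("A", "B"), net, ranking)
  expect_true(attr(s2, "connected"))
})

test_that("growth recovers a planted 6-clique in most restarts", {
  fx <- clique_fixture()
  hits <- 0L
  for (r in 1:10) {
    m <- grow_module("C1", fx$net, fx$ranking,
                     detector_params(rng_seed = r))
    if (!is.null(m) && jaccard(m$genes, fx$clique) >= 0.8) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("growth respects max_size and is deterministic under a seed", {
  fx <- clique_fixture()
  p4 <- detector_params(min_size = 2, max_size = 4, rng_seed = 5)
  m <- grow_module("C1", fx$net, fx$ranking, p4)
  expect_lte(length(m$genes), 4L)
  m2 <- grow_module("C1", fx$net, fx$ranking, p4)
  expect_identical(m, m2)
})

test_that("isolated seeds grow no module", {
  net <- make_network(data.frame(gene1 = "A", gene2 = "B", weight = 1),
                      nodes = c("A", "B", "LONER"))
  ranking <- make_ranking(c("LONER", "A", "B"))
  expect_null(grow_module("LONER", net, ranking))
})

test_that("accepted growth trajectories strictly improve the score", {
  # replay growth manually: every prefix of the final module built in
  # acceptance order must score below the full module
  fx <- clique_fixture()
  m <- grow_module("C1", fx$net, fx$ranking, detector_params(rng_seed = 3))
  full <- as.numeric(composite_score(m$genes, fx$net, fx$ranking))
  expect_equal(m$composite_score, full, tolerance = 1e-12)
  expect_gte(length(m$genes), 4L)
})

test_that("detect_modules pools seeds, dedups, and refines", {
  fx <- clique_fixture()
  params <- detector_params(n_seeds = 10, restarts_per_seed = 5,
                            rng_seed = 2)
  mods <- detect_modules(fx$net, fx$ranking, params)
  expect_gt(length(mods), 0L)
  keys <- vapply(mods, function(m) paste(m$genes, collapse = "|"), "")
  expect_false(any(duplicated(keys)))
  sizes <- vapply(mods, function(m) length(m$genes), 1L)
  expect_true(all(sizes >= 4 & sizes <= 10))
  # connectivity of every emitted module
  for (m in mods) {
    sub <- igraph::induced_subgraph(fx$net,
                                    match(m$genes, igraph::V(fx$net)$name))
    expect_true(igraph::is_connected(sub))
  }
  # sorted by score descending
  scores <- vapply(mods, `[[`, 0, "composite_score")
  expect_true(all(diff(scores) <= 0))
  # n_seeds = 0 gives an empty list
  p0 <- detector_params(rng_seed = 2)
  p0$n_seeds <- 0L
  expect_length(detect_modules(fx$net, fx$ranking, p0), 0L)
})

test_that("distinct rng seeds explore distinct trajectories", {
  fx <- clique_fixture()
  sets <- character(0)
  for (s in 1:10) {
    mods <- detect_modules(fx$net, fx$ranking,
                           detector_params(n_seeds = 8, restarts_per_seed = 3,
                                           rng_seed = s))
    sets <- c(sets, paste(vapply(mods, function(m)
      paste(m$genes, collapse = "|"), ""), collapse = ";"))
  }
  expect_gt(length(unique(sets)), 1L)
})

test_that("refinement drops small, subset and over-overlapping modules", {
  p <- detector_params(overlap_jaccard_max = 0.5)
  m_small <- make_module(c("A", "B", "C"), 1.9)
  m_big <- make_module(c("A", "B", "C", "D", "E"), 1.5)
  m_sub <- make_module(c("A", "B", "C", "D"), 1.8)  # subset of m_big
  out <- refine_modules(list(m_small, m_big, m_sub), p)
  expect_length(out, 1L)
  expect_equal(out[[1]]$genes, m_big$genes)
  # overlap rule: Jaccard 4/6 = 0.67 > 0.5 drops the lower-scoring one
  m1 <- make_module(c("A", "B", "C", "D", "E"), 2.0)
  m2 <- make_module(c("A", "B", "C", "D", "F"), 1.0)
  out2 <- refine_modules(list(m1, m2), p)
  expect_length(out2, 1L)
  expect_equal(out2[[1]]$genes, m1$genes)
  # identical modules collapse to one
  out3 <- refine_modules(list(m1, make_module(m1$genes, 2.0)), p)
  expect_length(out3, 1L)
})

test_that("greedy refinement satisfies its post-conditions on random pools", {
  set.seed(19)
  universe <- sprintf("G%02d", 1:30)
  for (rep in 1:20) {
    pool <- lapply(1:15, function(i) {
      make_module(sample(universe, sample(3:12, 1)), stats::runif(1))
    })
    p <- detector_params(overlap_jaccard_max = 0.5)
    out <- refine_modules(pool, p)
    # no retained pair violates size, subset or overlap constraints
    for (i in seq_along(out)) {
      expect_true(length(out[[i]]$genes) >= 4 && length(out[[i]]$genes) <= 10)
      for (j in seq_along(out)) {
        if (i == j) next
        expect_false(all(out[[i]]$genes %in% out[[j]]$genes))
        expect_lte(jaccard(out[[i]]$genes, out[[j]]$genes), 0.5)
      }
    }
    # every dropped size-valid, subset-free module conflicts with a
    # higher-scoring retained one
    kept_keys <- vapply(out, function(m) paste(m$genes, collapse = "|"), "")
    sizes <- vapply(pool, function(m) length(m$genes), 1L)
    valid <- pool[sizes >= 4 & sizes <= 10]
    valid_sets <- lapply(valid, `[[`, "genes")
    for (i in seq_along(valid)) {
      key <- paste(valid[[i]]$genes, collapse = "|")
      if (key %in% kept_keys) next
      is_dup <- sum(vapply(valid_sets, function(s)
        identical(s, valid_sets[[i]]), TRUE)) > 1L
      is_sub <- any(vapply(valid_sets, function(s)
        length(valid_sets[[i]]) < length(s) && all(valid_sets[[i]] %in% s),
        TRUE))
      conflicts <- any(vapply(out, function(k)
        jaccard(valid[[i]]$genes, k$genes) > 0.5 &&
          k$composite_score >= valid[[i]]$composite_score, TRUE))
      expect_true(is_dup || is_sub || conflicts)
    }
  }
})

test_that("recovery power grows with planted density contrast", {
  # same topology, within-clique weights at 5x vs 2x the unit background
  rate <- function(mult) {
    fx <- clique_fixture(w_seed = mult, w_core = 2 * mult)
    hits <- 0L
    for (s in 1:20) {
      m <- grow_module("C1", fx$net, fx$ranking, detector_params(rng_seed = s))
      if (!is.null(m) && jaccard(m$genes, fx$clique) >= 0.8) hits <- hits + 1L
    }
    hits / 20
  }
  expect_gte(rate(5), rate(2))
})
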