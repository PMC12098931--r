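# Monte-Carlo seed-and-extend module detection. Starting from each
# high-ranked seed gene, a module grows by stochastically proposing
# neighbours (probability proportional to their total edge weight into the
# module) and accepting a proposal only if it strictly improves the
# composite score. The pooled candidates are then refined: size constrained
# to 4-10 genes, redundant subsets removed, and overlapping modules
# resolved greedily by score.

#' Detection parameters
#'
#' @param n_seeds Number of top-ranked genes used as growth seeds.
#' @param min_size,max_size Module size bounds retained after refinement
#'   (defaults 4 and 10).
#' @param restarts_per_seed Independent stochastic growths per seed.
#' @param patience Consecutive rejected proposals before a growth stops.
#' @param overlap_jaccard_max Maximum Jaccard overlap allowed between two
#'   retained modules.
#' @param rng_seed Integer seed controlling all stochastic growth.
#' @return A list of class `detector_params`.
#' @export
detector_params <- function(n_seeds = 50, min_size = 4, max_size = 10,
                            restarts_per_seed = 20, patience = 15,
                            overlap_jaccard_max = 0.5, rng_seed = 1) {
  if (min_size >= max_size) config_error("min_size must be < max_size")
  if (restarts_per_seed < 1) config_error("restarts_per_seed must be >= 1")
  if (patience < 1) config_error("patience must be >= 1")
  if (n_seeds < 0) config_error("n_seeds must be >= 0")
  if (overlap_jaccard_max <= 0 || overlap_jaccard_max > 1) {
    config_error("overlap_jaccard_max must be in (0, 1]")
  }
  structure(list(n_seeds = as.integer(n_seeds),
                 min_size = as.integer(min_size),
                 max_size = as.integer(max_size),
                 restarts_per_seed = as.integer(restarts_per_seed),
                 patience = as.integer(patience),
                 overlap_jaccard_max = overlap_jaccard_max,
                 rng_seed = as.integer(rng_seed)),
            class = "detector_params")
}

#' Jaccard overlap of two gene sets
#'
#' @param a,b Character vectors of gene symbols.
#' @return `|a intersect b| / |a union b|`.
#' @export
jaccard <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

# Precompute what the growth loop needs: dense weight matrix, neighbour
# index lists, per-gene rank quality in [0, 1], and the maximum edge weight.
module_workspace <- function(network, ranking) {
  genes <- igraph::V(network)$name
  n <- length(genes)
  W <- matrix(0, n, n, dimnames = list(genes, genes))
  if (igraph::ecount(network) > 0L) {
    el <- igraph::as_edgelist(network, names = FALSE)
    w <- igraph::E(network)$weight
    W[cbind(el[, 1], el[, 2])] <- w
    W[cbind(el[, 2], el[, 1])] <- w
  }
  nbrs <- lapply(seq_len(n), function(i) which(W[i, ] > 0))
  nr <- nrow(ranking)
  quality <- rep(NA_real_, n)
  idx <- match(ranking$gene, genes)
  quality[idx[!is.na(idx)]] <-
    if (nr > 1L) 1 - (ranking$rank[!is.na(idx)] - 1) / (nr - 1) else 1
  list(genes = genes, W = W, nbrs = nbrs, quality = quality,
       max_w = if (any(W > 0)) max(W) else 1)
}

# Composite score on integer node indices (fast path used during growth).
composite_score_idx <- function(idx, ws) {
  k <- length(idx)
  sub <- ws$W[idx, idx, drop = FALSE]
  density <- sum(sub) / 2 / (choose(k, 2) * ws$max_w)
  density + mean(ws$quality[idx])
}

#' Composite quality score of a gene set
#'
#' The score is the sum of two terms in `[0, 1]` each: a density term, the
#' mean internal edge weight over all `C(k,2)` gene pairs normalized by the
#' network's maximum edge weight, and a rank term, the mean over member
#' genes of `1 - (rank - 1)/(n_genes - 1)`. A disconnected gene set is
#' scored but flagged via the `connected` attribute.
#'
#' @param genes Character vector of at least two network genes.
#' @param network The `igraph` gene network.
#' @param ranking A `ranked_genes` data frame covering the genes.
#' @return Numeric score in `[0, 2]` with logical attribute `connected`.
#' @export
composite_score <- function(genes, network, ranking) {
  genes <- unique(genes)
  if (length(genes) < 2L) {
    validation_error("composite_score needs at least 2 genes")
  }
  ws <- module_workspace(network, ranking)
  idx <- match(genes, ws$genes)
  if (anyNA(idx)) {
    validation_error("gene(s) not in network: %s",
                     paste(genes[is.na(idx)], collapse = ", "))
  }
  if (anyNA(ws$quality[idx])) {
    validation_error("gene(s) missing from ranking")
  }
  score <- composite_score_idx(idx, ws)
  sub <- igraph::induced_subgraph(network, idx)
  connected <- igraph::is_connected(sub)
  if (!connected) dm_log("scored a disconnected gene set")
  structure(score, connected = connected)
}

# Core growth loop on a precomputed workspace. Returns integer indices or
# NULL when no state with >= 2 genes was accepted.
grow_module_idx <- function(seed_idx, ws, params) {
  m <- seed_idx
  in_m <- rep(FALSE, length(ws$genes))
  in_m[seed_idx] <- TRUE
  # Singleton baseline: rank term only (the density term needs >= 2 genes),
  # so the first accepted neighbour must add enough density to beat it.
  cur <- ws$quality[seed_idx]
  rejections <- 0L
  while (length(m) < params$max_size) {
    cand <- unique(unlist(ws$nbrs[m], use.names = FALSE))
    cand <- cand[!in_m[cand]]
    cand <- cand[!is.na(ws$quality[cand])]
    if (length(cand) == 0L) break
    wts <- colSums(ws$W[m, cand, drop = FALSE])
    c_idx <- if (length(cand) == 1L) cand else
      sample(cand, 1L, prob = wts)
    cand_score <- composite_score_idx(c(m, c_idx), ws)
    if (cand_score > cur) {
      m <- c(m, c_idx)
      in_m[c_idx] <- TRUE
      cur <- cand_score
      rejections <- 0L
    } else {
      rejections <- rejections + 1L
      if (rejections >= params$patience) break
    }
  }
  if (length(m) < 2L) NULL else m
}

new_module <- function(idx, seed_idx, ws) {
  structure(list(genes = sort(ws$genes[idx]), seed = ws$genes[seed_idx],
                 composite_score = composite_score_idx(idx, ws),
                 enrichment = NULL, significant = NA),
            class = "gene_module")
}

#' Grow a single candidate module from a seed gene
#'
#' Starting from `m = {seed}`, repeatedly samples one neighbour of the
#' current module with probability proportional to its total edge weight
#' into the module, and accepts it only if the composite score strictly
#' improves. Growth stops after `patience` consecutive rejections or at
#' `max_size` genes. Because acceptance is strict-improvement, the final
#' state is the best-scoring state visited.
#'
#' @param seed A network gene symbol with degree >= 1.
#' @param network The `igraph` gene network.
#' @param ranking A `ranked_genes` data frame.
#' @param params A `detector_params` object (its `rng_seed` seeds this
#'   growth).
#' @return A `gene_module` (fields `genes`, `seed`, `composite_score`,
#'   `enrichment`, `significant`) or `NULL` if no two-gene state was
#'   reached.
#' @export
grow_module <- function(seed, network, ranking, params = detector_params()) {
  ws <- module_workspace(network, ranking)
  seed_idx <- match(norm_symbol(seed), ws$genes)
  if (is.na(seed_idx)) validation_error("seed gene '%s' not in network", seed)
  if (length(ws$nbrs[[seed_idx]]) == 0L) {
    dm_log("seed '%s' is isolated; no module grown", seed)
    return(NULL)
  }
  idx <- with_rng_seed(params$rng_seed, grow_module_idx(seed_idx, ws, params))
  if (is.null(idx)) return(NULL)
  new_module(idx, seed_idx, ws)
}

#' Detect candidate modules across all seeds
#'
#' Runs `restarts_per_seed` independent growths from each of the top
#' `n_seeds` ranked genes (isolated seeds are skipped), pools the results,
#' deduplicates identical gene sets, and applies [refine_modules()]. All
#' randomness is governed by `params$rng_seed`.
#'
#' @param network The `igraph` gene network.
#' @param ranking A `ranked_genes` data frame covering the network nodes.
#' @param params A `detector_params` object.
#' @return List of `gene_module` objects sorted by composite score
#'   descending.
#' @export
detect_modules <- function(network, ranking, params = detector_params()) {
  if (igraph::vcount(network) == 0L) return(list())
  ws <- module_workspace(network, ranking)
  seeds <- ranking$gene[seq_len(min(params$n_seeds, nrow(ranking)))]
  seed_idx <- match(seeds, ws$genes)
  seed_idx <- seed_idx[!is.na(seed_idx)]
  seed_idx <- seed_idx[vapply(ws$nbrs[seed_idx], length, 1L) > 0L]
  if (length(seed_idx) == 0L) return(list())
  pool <- with_rng_seed(params$rng_seed, {
    out <- list()
    for (s in seed_idx) {
      for (r in seq_len(params$restarts_per_seed)) {
        idx <- grow_module_idx(s, ws, params)
        if (!is.null(idx)) out[[length(out) + 1L]] <- new_module(idx, s, ws)
      }
    }
    out
  })
  dm_log("pooled %d grown modules from %d seeds", length(pool),
         length(seed_idx))
  refine_modules(pool, params)
}

#' Refine a pool of candidate modules
#'
#' In order: (1) deduplicate identical gene sets; (2) drop modules outside
#' the `[min_size, max_size]` gene range; (3) drop any module whose gene
#' set is a strict subset of another surviving module's; (4) process the
#' remainder in score-descending order (ties broken by gene-set string),
#' dropping any module whose Jaccard overlap with an already-retained one
#' exceeds `overlap_jaccard_max`.
#'
#' @param modules List of `gene_module` objects.
#' @param params A `detector_params` object.
#' @return Refined list sorted by composite score descending.
#' @export
refine_modules <- function(modules, params = detector_params()) {
  if (length(modules) == 0L) return(list())
  keys <- vapply(modules, function(m) paste(sort(m$genes), collapse = "|"), "")
  modules <- modules[!duplicated(keys)]
  sizes <- vapply(modules, function(m) length(m$genes), 1L)
  modules <- modules[sizes >= params$min_size & sizes <= params$max_size]
  if (length(modules) == 0L) return(list())
  gene_sets <- lapply(modules, `[[`, "genes")
  is_subset <- vapply(seq_along(modules), function(i) {
    any(vapply(seq_along(modules), function(j) {
      i != j && length(gene_sets[[i]]) < length(gene_sets[[j]]) &&
        all(gene_sets[[i]] %in% gene_sets[[j]])
    }, TRUE))
  }, TRUE)
  modules <- modules[!is_subset]
  scores <- vapply(modules, `[[`, 0, "composite_score")
  keys <- vapply(modules, function(m) paste(m$genes, collapse = "|"), "")
  modules <- modules[order(-scores, keys)]
  kept <- list()
  for (m in modules) {
    ok <- all(vapply(kept, function(k) {
      jaccard(m$genes, k$genes) <= params$overlap_jaccard_max
    }, TRUE))
    if (ok) kept[[length(kept) + 1L]] <- m
  }
  kept
}
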