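# End-to-end pipeline: load inputs, build the network, rank genes, detect
# and enrich modules, evaluate against benchmarks, and serialize a result
# bundle (GraphML + edge list, feature and ranking TSVs, module and
# evaluation JSON, and a run manifest with input checksums).

default_config <- function() {
  list(
    mutations = NULL, annotations = NULL, annotation_format = "two-column",
    benchmark_gmt = NULL, pathways_gmt = NULL,
    gene_column = "gene", count_column = "count",
    top_n = 200, alpha = 0.05, min_enriched = 2,
    folds = 5, n_random = 99, rng_seed = 1,
    n_seeds = 50, restarts_per_seed = 20, patience = 15,
    overlap_jaccard_max = 0.5, min_size = 4, max_size = 10
  )
}

#' Read a flat key-value configuration file
#'
#' Lines have the form `key = value`; blank lines and lines starting with
#' `#` are ignored. Numeric-looking values are converted to numbers.
#'
#' @param path Path to the configuration file.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) validation_error("config file not found: %s", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) validation_error("malformed config line: '%s'", ln)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_config(config)
  }
  cfg <- default_config()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown) > 0L) {
    config_error("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg[names(config)] <- config
  if (cfg$top_n < 1) config_error("top_n must be a positive integer")
  for (key in c("mutations", "annotations")) {
    if (is.null(cfg[[key]])) config_error("config key '%s' is required", key)
    if (!file.exists(cfg[[key]])) {
      config_error("input file for '%s' not found: %s", key, cfg[[key]])
    }
  }
  for (key in c("benchmark_gmt", "pathways_gmt")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      config_error("input file for '%s' not found: %s", key, cfg[[key]])
    }
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Loads the configured inputs, selects nodes, builds the weighted network,
#' computes topology features, ranks genes, detects and refines modules,
#' scores pathway enrichment (when a pathway GMT is configured) and
#' evaluates the ranking against each configured benchmark set. All
#' artifacts are written under `out_dir`:
#' `network.graphml`, `network_edges.tsv`, `features.tsv`, `ranking.tsv`,
#' `modules.json`, `evaluation.json` and `manifest.json`. Reruns with the
#' same configuration produce identical ranking and module files. If any
#' stage fails, a `FAILED` marker file holding the error message is left
#' in `out_dir`.
#'
#' @param config Named list of options or path to a flat key-value config
#'   file. Required keys: `mutations`, `annotations`. Optional:
#'   `benchmark_gmt`, `pathways_gmt`, `annotation_format`, `top_n`,
#'   `alpha`, `min_enriched`, `folds`, `n_random`, `rng_seed`, `n_seeds`,
#'   `restarts_per_seed`, `patience`, `overlap_jaccard_max`, `min_size`,
#'   `max_size`, `gene_column`, `count_column`.
#' @param out_dir Output directory for the result bundle.
#' @param stages Last stage to run: one of `"network"`, `"rank"`,
#'   `"modules"`, `"enrich"`, `"evaluate"` (default; runs everything).
#' @return Invisibly, a list with the in-memory results (`network`,
#'   `features`, `ranking`, `modules`, `evaluation`, `paths`).
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("evaluate", "enrich", "modules",
                                    "rank", "network")) {
  stages <- match.arg(stages)
  stage_rank <- c(network = 1, rank = 2, modules = 3, enrich = 4,
                  evaluate = 5)
  upto <- stage_rank[[stages]]
  cfg <- resolve_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(out_dir, "FAILED")
  if (file.exists(marker)) unlink(marker)
  res <- tryCatch(
    run_pipeline_impl(cfg, out_dir, upto),
    error = function(e) {
      writeLines(conditionMessage(e), marker)
      stop(e)
    }
  )
  invisible(res)
}

run_pipeline_impl <- function(cfg, out_dir, upto) {
  paths <- list(
    network_graphml = file.path(out_dir, "network.graphml"),
    network_edges = file.path(out_dir, "network_edges.tsv"),
    features = file.path(out_dir, "features.tsv"),
    ranking = file.path(out_dir, "ranking.tsv"),
    modules = file.path(out_dir, "modules.json"),
    evaluation = file.path(out_dir, "evaluation.json"),
    manifest = file.path(out_dir, "manifest.json")
  )
  records <- load_mutation_table(cfg$mutations, cfg$gene_column,
                                 cfg$count_column)
  annotations <- load_annotations(cfg$annotations, cfg$annotation_format)
  selection <- select_nodes(records, annotations, top_n = cfg$top_n)
  network <- build_network(selection, annotations)
  igraph::write_graph(network, paths$network_graphml, format = "graphml")
  el <- igraph::as_edgelist(network)
  edges <- data.frame(gene1 = el[, 1], gene2 = el[, 2],
                      weight = if (igraph::ecount(network) > 0)
                        igraph::E(network)$weight else integer(0))
  edges <- edges[order(edges$gene1, edges$gene2), , drop = FALSE]
  write.table(edges, paths$network_edges, sep = "\t", quote = FALSE,
              row.names = FALSE)
  features <- compute_topology_features(network)
  write.table(features, paths$features, sep = "\t", quote = FALSE,
              row.names = FALSE)
  out <- list(network = network, features = features, ranking = NULL,
              modules = NULL, evaluation = NULL, paths = paths, config = cfg)
  if (upto >= 2) {
    ls <- laplacian_feature_scores(features, network)
    ranking <- rank_genes(features, ls, network)
    write.table(ranking, paths$ranking, sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$ranking <- ranking
  }
  if (upto >= 3) {
    params <- detector_params(
      n_seeds = cfg$n_seeds, min_size = cfg$min_size,
      max_size = cfg$max_size, restarts_per_seed = cfg$restarts_per_seed,
      patience = cfg$patience, overlap_jaccard_max = cfg$overlap_jaccard_max,
      rng_seed = cfg$rng_seed)
    modules <- detect_modules(out$network, out$ranking, params)
    out$modules <- modules
  }
  if (upto >= 4 && !is.null(cfg$pathways_gmt) && !is.null(out$modules)) {
    pathways <- load_gmt(cfg$pathways_gmt)
    universe <- igraph::V(out$network)$name
    out$modules <- lapply(out$modules, evaluate_module, pathways = pathways,
                          universe = universe, alpha = cfg$alpha,
                          min_enriched = cfg$min_enriched)
  }
  if (upto >= 3) {
    jsonlite::write_json(
      lapply(out$modules, function(m) {
        list(genes = m$genes, seed = jsonlite::unbox(m$seed),
             composite_score = jsonlite::unbox(m$composite_score),
             significant = jsonlite::unbox(m$significant),
             enrichment = m$enrichment)
      }),
      paths$modules, digits = NA, pretty = TRUE, na = "null")
  }
  if (upto >= 5 && !is.null(cfg$benchmark_gmt)) {
    benchmarks <- load_gmt(cfg$benchmark_gmt)
    reports <- lapply(benchmarks, function(b) {
      rep <- evaluate_ranking(out$ranking, b, folds = cfg$folds,
                              n_random = cfg$n_random,
                              rng_seed = cfg$rng_seed)
      unclass(rep)
    })
    names(reports) <- vapply(benchmarks, `[[`, "", "name")
    out$evaluation <- reports
    jsonlite::write_json(reports, paths$evaluation, digits = NA,
                         auto_unbox = TRUE, pretty = TRUE, na = "null")
  }
  inputs <- Filter(Negate(is.null),
                   cfg[c("mutations", "annotations", "benchmark_gmt",
                         "pathways_gmt")])
  manifest <- list(
    package = "drivermod",
    version = as.character(utils::packageVersion("drivermod")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = Filter(Negate(is.null), cfg),
    rng_seed = cfg$rng_seed,
    input_md5 = as.list(tools::md5sum(unlist(inputs)))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, na = "null")
  out
}

#' Query a gene in a result bundle
#'
#' Returns the gene's rank, composite score, five topological features and
#' every retained module containing it. Unknown genes raise a not-found
#' error listing the nearest symbol matches.
#'
#' @param gene A gene symbol.
#' @param bundle_dir A directory written by [run_pipeline()].
#' @return A list of class `gene_report` with fields `gene`, `rank`,
#'   `score`, `features` (named numeric vector) and `modules` (list of
#'   module entries containing the gene).
#' @export
gene_info <- function(gene, bundle_dir) {
  ranking_path <- file.path(bundle_dir, "ranking.tsv")
  features_path <- file.path(bundle_dir, "features.tsv")
  modules_path <- file.path(bundle_dir, "modules.json")
  if (!file.exists(ranking_path)) {
    validation_error("no ranking found in bundle %s", bundle_dir)
  }
  gene <- norm_symbol(gene)
  ranking <- read.delim(ranking_path, stringsAsFactors = FALSE)
  if (!gene %in% ranking$gene) {
    near <- agrep(gene, ranking$gene, max.distance = 0.25, value = TRUE)
    validation_error("gene '%s' not found in bundle%s", gene,
                     if (length(near) > 0)
                       paste0("; nearest matches: ",
                              paste(head(near, 5), collapse = ", "))
                     else "")
  }
  row <- ranking[ranking$gene == gene, ]
  feats <- NULL
  if (file.exists(features_path)) {
    ft <- read.delim(features_path, stringsAsFactors = FALSE)
    fr <- ft[ft$gene == gene, setdiff(names(ft), "gene"), drop = FALSE]
    feats <- unlist(fr[1L, ])
  }
  mods <- list()
  if (file.exists(modules_path)) {
    all_mods <- jsonlite::read_json(modules_path, simplifyVector = FALSE)
    mods <- Filter(function(m) gene %in% unlist(m$genes), all_mods)
  }
  structure(list(gene = gene, rank = row$rank[1L], score = row$score[1L],
                 features = feats, modules = mods),
            class = "gene_report")
}

#' @export
print.gene_report <- function(x, ...) {
  cat(sprintf("Gene %s: rank %d, score %.4f\n", x$gene, x$rank, x$score))
  if (!is.null(x$features)) {
    cat("Features:\n")
    for (nm in names(x$features)) {
      cat(sprintf("  %-12s %.6g\n", nm, x$features[[nm]]))
    }
  }
  if (length(x$modules) > 0) {
    cat(sprintf("Member of %d module(s):\n", length(x$modules)))
    for (m in x$modules) {
      cat(sprintf("  [%s] score %.4f%s\n",
                  paste(unlist(m$genes), collapse = ", "),
                  m$composite_score,
                  if (isTRUE(m$significant)) " (significant)" else ""))
    }
  } else {
    cat("Not a member of any retained module.\n")
  }
  invisible(x)
}
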