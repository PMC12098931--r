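# Readers for the external inputs: mutation-frequency tables, gene ->
# biological-process annotations (two-column TSV or GAF 2.x restricted to
# aspect "P"), and GMT gene sets. All readers accept plain or gzip files
# (R connections decompress transparently) and normalize gene symbols to
# uppercase with surrounding whitespace stripped.

#' Load a per-cancer gene mutation-frequency table
#'
#' Reads a tab- or comma-delimited table with a header row, normalizes gene
#' symbols, merges duplicate symbols by summing their counts, and sorts by
#' mutation count descending (ties broken by symbol ascending).
#'
#' @param path Path to a TSV/CSV file (optionally gzip-compressed).
#' @param gene_column Name of the gene-symbol column.
#' @param count_column Name of the mutation count/frequency column. Values
#'   are unit-agnostic (raw counts or frequencies) but must be non-negative.
#' @return A `data.frame` of class `mutation_table` with columns `gene` and
#'   `mutation_count`, one row per distinct symbol, sorted as described.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tcount", "TP53\t120", "KRAS\t80", "TP53\t5"), tf)
#' load_mutation_table(tf)
#' @export
load_mutation_table <- function(path, gene_column = "gene",
                                count_column = "count") {
  if (!file.exists(path)) validation_error("mutation table not found: %s", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) validation_error("mutation table is empty: %s", path)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  tab <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (col in c(gene_column, count_column)) {
    if (!col %in% names(tab)) {
      config_error("column '%s' not present in %s (found: %s)",
                   col, path, paste(names(tab), collapse = ", "))
    }
  }
  if (nrow(tab) == 0L) validation_error("mutation table has no data rows: %s", path)
  gene <- norm_symbol(tab[[gene_column]])
  count <- suppressWarnings(as.numeric(tab[[count_column]]))
  bad <- which(is.na(count) | count < 0)
  if (length(bad) > 0L) {
    validation_error("negative or non-numeric mutation count at data row %d",
                     bad[1L])
  }
  empty <- which(!nzchar(gene))
  if (length(empty) > 0L) {
    validation_error("empty gene symbol at data row %d", empty[1L])
  }
  agg <- tapply(count, gene, sum)
  out <- data.frame(gene = names(agg), mutation_count = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mutation_count, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mutation_table", "data.frame")
  dm_log("loaded %d gene records from %s (%d input rows)", nrow(out), path,
         nrow(tab))
  out
}

# Build a consistent bidirectional annotation map from (gene, process) pairs.
annotation_map <- function(gene, process) {
  keep <- nzchar(gene) & nzchar(process)
  gene <- gene[keep]; process <- process[keep]
  key <- paste0(gene, "\r", process)
  dup <- duplicated(key)
  gene <- gene[!dup]; process <- process[!dup]
  if (length(gene) == 0L) {
    validation_error("no usable (gene, process) annotation pairs")
  }
  g2p <- lapply(split(process, gene), function(p) sort(unique(p)))
  p2g <- lapply(split(gene, process), function(g) sort(unique(g)))
  structure(list(gene_to_processes = g2p, process_to_genes = p2g),
            class = "annotation_map")
}

#' Load gene-to-biological-process annotations
#'
#' Two formats are supported. `"two-column"` is a headerless TSV of
#' `(gene, process-ID)` pairs, one per line. `"gaf"` is GAF 2.x, from which
#' only rows with aspect `"P"` (biological process) are retained and rows
#' whose qualifier contains `"NOT"` are dropped; malformed lines (fewer than
#' 15 tab fields) are skipped with a warning and counted.
#'
#' Duplicate pairs are collapsed. The result keeps the forward and inverse
#' mappings exactly consistent and stores no empty process sets.
#'
#' @param path Path to the annotation file (optionally gzip-compressed).
#' @param format `"two-column"` or `"gaf"`.
#' @return An `annotation_map`: a list with elements `gene_to_processes`
#'   (named list symbol -> character vector of process IDs) and
#'   `process_to_genes` (the exact inverse).
#' @export
load_annotations <- function(path, format = c("two-column", "gaf")) {
  format <- match.arg(format)
  if (!file.exists(path)) validation_error("annotation file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (format == "two-column") {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- vapply(parts, length, 1L) < 2L
    if (any(bad)) {
      warning(sprintf("skipped %d malformed annotation line(s)", sum(bad)))
      parts <- parts[!bad]
    }
    gene <- norm_symbol(vapply(parts, `[[`, "", 1L))
    process <- trimws(vapply(parts, `[[`, "", 2L))
  } else {
    lines <- lines[!startsWith(lines, "!")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- vapply(parts, length, 1L)
    skipped <- sum(nf < 15L)
    if (skipped > 0L) {
      warning(sprintf("skipped %d malformed GAF line(s) (< 15 fields)", skipped))
    }
    parts <- parts[nf >= 15L]
    qualifier <- vapply(parts, `[[`, "", 4L)
    aspect <- vapply(parts, `[[`, "", 9L)
    keep <- aspect == "P" & !grepl("NOT", qualifier, fixed = TRUE)
    parts <- parts[keep]
    gene <- norm_symbol(vapply(parts, `[[`, "", 3L))
    process <- trimws(vapply(parts, `[[`, "", 5L))
    dm_log("GAF: retained %d aspect-P rows (%d skipped malformed)",
           length(gene), skipped)
  }
  if (length(gene) == 0L) {
    validation_error("no usable annotation pairs in %s", path)
  }
  map <- annotation_map(gene, process)
  dm_log("loaded annotations: %d genes, %d processes",
         length(map$gene_to_processes), length(map$process_to_genes))
  map
}

#' Construct a gene set
#'
#' Symbols are normalized (uppercase, whitespace-stripped), deduplicated
#' and sorted; an empty set is a validation error.
#'
#' @param name Set name.
#' @param genes Character vector of gene symbols.
#' @param description Optional free-text description.
#' @return A list of class `gene_set` with fields `name`, `description`,
#'   `genes`.
#' @export
gene_set <- function(name, genes, description = "") {
  genes <- sort(unique(norm_symbol(genes)))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) validation_error("gene set '%s' is empty", name)
  structure(list(name = name, description = description, genes = genes),
            class = "gene_set")
}

#' Load gene sets from a GMT file
#'
#' Each line is `name TAB description TAB gene1 TAB gene2 ...`. Duplicate
#' genes within a line are collapsed; a line with fewer than three fields is
#' a validation error reported with its line number.
#'
#' @param path Path to a GMT file (optionally gzip-compressed).
#' @return A list of `gene_set` objects (fields `name`, `description`,
#'   `genes`).
#' @export
load_gmt <- function(path) {
  if (!file.exists(path)) validation_error("GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) validation_error("GMT file is empty: %s", path)
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      validation_error("GMT line %d has fewer than 3 fields", i)
    }
    out[[i]] <- gene_set(fields[1L], fields[-(1:2)], description = fields[2L])
  }
  dm_log("loaded %d gene sets from %s", length(out), path)
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets A list of `gene_set` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
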