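# Readers and writers for the external formats: dense / Matrix Market
# expression matrices, GMT gene-set dictionaries, edge lists, and network
# exports (GraphML, JSON, edge TSV).
#
# All readers apply the same gene-id normalization (trim + uppercase,
# disable with normalize = FALSE) so joins across files never fail on case.

#' Read an expression matrix
#'
#' Two formats are supported: `"dense"` — a tab-delimited table whose first
#' column holds gene ids and whose header row holds cell ids — and `"mtx"` —
#' Matrix Market coordinate format with one-id-per-line sidecar files for
#' row (gene) and column (cell) names. With `format = "auto"` files ending
#' in `.mtx` are treated as Matrix Market.
#'
#' Cluster labels come from `clusters_path`: either one label per line
#' (ordered as the cells) or a two-column table `cell_id<TAB>label`. When
#' absent, a `<path>.clusters` sidecar is picked up if it exists, else all
#' cells fall in a single cluster `"all"`.
#'
#' @param path Path to the matrix file.
#' @param format One of `"auto"`, `"dense"`, `"mtx"`.
#' @param genes_path,cells_path Sidecar files with row/column ids for
#'   `"mtx"` input; default to `<path>.genes` and `<path>.cells`.
#' @param clusters_path Optional cluster-label file (see Details).
#' @param transpose For `"mtx"` input whose matrix is stored cells x genes,
#'   transpose after reading. Genes-as-rows is the default orientation.
#' @param normalize Normalize gene ids (trim whitespace, uppercase).
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("auto", "dense", "mtx"),
                            genes_path = NULL, cells_path = NULL,
                            clusters_path = NULL, transpose = FALSE,
                            normalize = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "dense"
  }
  if (format == "dense") {
    tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    gene_ids <- as.character(tab[[1]])
    values <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(values) <- "double"
    cell_ids <- colnames(values)
  } else {
    genes_path <- genes_path %||% paste0(path, ".genes")
    cells_path <- cells_path %||% paste0(path, ".cells")
    if (!file.exists(genes_path)) stopf("gene sidecar not found: %s", genes_path)
    if (!file.exists(cells_path)) stopf("cell sidecar not found: %s", cells_path)
    values <- as.matrix(Matrix::readMM(path))
    if (transpose) values <- t(values)
    gene_ids <- readLines(genes_path)
    cell_ids <- readLines(cells_path)
  }
  gene_ids <- normalize_ids(gene_ids, normalize)
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(as.matrix(neg)) > 0) {
    neg <- as.matrix(neg)
    stopf("negative value in %s at row %d (gene '%s'), column %d",
          path, neg[1, 1], gene_ids[neg[1, 1]], neg[1, 2])
  }
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup) > 0) {
    stopf("duplicate gene id(s) in %s: %s", path, paste(dup, collapse = ", "))
  }
  clusters <- read_cluster_labels(clusters_path, path, cell_ids)
  expression_matrix(values, gene_ids, cell_ids, clusters)
}

#' @noRd
read_cluster_labels <- function(clusters_path, matrix_path, cell_ids) {
  if (is.null(clusters_path)) {
    candidate <- paste0(matrix_path, ".clusters")
    if (file.exists(candidate)) clusters_path <- candidate
  }
  if (is.null(clusters_path)) return(rep("all", length(cell_ids)))
  lines <- readLines(clusters_path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (all(lengths(parts) == 1)) {
    if (length(lines) != length(cell_ids)) {
      stopf("cluster file %s has %d labels for %d cells",
            clusters_path, length(lines), length(cell_ids))
    }
    return(lines)
  }
  ids <- vapply(parts, `[`, character(1), 1)
  labs <- vapply(parts, `[`, character(1), 2)
  idx <- match(cell_ids, ids)
  if (anyNA(idx)) {
    stopf("cluster file %s missing label for cell '%s'",
          clusters_path, cell_ids[which(is.na(idx))[1]])
  }
  labs[idx]
}

#' Write an expression matrix
#'
#' The inverse of [read_expression()]. Cluster labels are always written to
#' a `<path>.clusters` sidecar (cell_id, label) so a round trip restores
#' the full object.
#'
#' @param expr An [expression_matrix()].
#' @param path Output path.
#' @param format `"dense"` or `"mtx"` (Matrix Market plus `.genes`/`.cells`
#'   sidecars).
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expr, path, format = c("dense", "mtx")) {
  format <- match.arg(format)
  if (format == "dense") {
    tab <- data.frame(gene = expr$gene_ids, expr$values, check.names = FALSE,
                      stringsAsFactors = FALSE)
    colnames(tab) <- c("gene", expr$cell_ids)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(expr$values, sparse = TRUE), path)
    writeLines(expr$gene_ids, paste0(path, ".genes"))
    writeLines(expr$cell_ids, paste0(path, ".cells"))
  }
  utils::write.table(
    data.frame(cell = expr$cell_ids, cluster = expr$cluster_labels),
    paste0(path, ".clusters"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file into an annotation dictionary
#'
#' Standard GMT: one term per line, tab-separated
#' `term_id<TAB>description<TAB>gene1<TAB>gene2...`. Empty gene fields are
#' dropped and duplicate genes within a term deduplicated.
#'
#' @param path Path to the GMT file.
#' @param normalize Normalize gene ids (trim + uppercase).
#' @return An [annotation_dictionary()].
#' @export
read_gmt <- function(path, normalize = TRUE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  keep <- nzchar(lines)
  lines <- lines[keep]
  line_no <- which(keep)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    stopf("GMT line %d has fewer than 3 tab-separated fields", line_no[bad[1]])
  }
  ids <- vapply(parts, `[`, character(1), 1)
  labels <- vapply(parts, `[`, character(1), 2)
  sets <- lapply(parts, function(p) {
    g <- normalize_ids(p[-(1:2)], normalize)
    unique(g[nzchar(g)])
  })
  names(sets) <- ids
  annotation_dictionary(sets, stats::setNames(labels, ids))
}

#' Write an annotation dictionary as GMT
#'
#' @param dict An [annotation_dictionary()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(dict, path) {
  lines <- vapply(names(dict$sets), function(id) {
    paste(c(id, dict$labels[[id]], dict$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an undirected edge list (e.g. a ground-truth network)
#'
#' Whitespace-separated lines `gene_a gene_b [weight]`; a missing weight
#' defaults to 1. Pairs are undirected: `a b` and `b a` are the same edge
#' and the first occurrence wins. Self-pairs are skipped with a warning.
#'
#' @param path Path to the edge-list file.
#' @param normalize Normalize gene ids (trim + uppercase).
#' @return A [gene_network()].
#' @export
read_edge_list <- function(path, normalize = TRUE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0) return(gene_network())
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(parts) < 2)
  if (length(bad) > 0) {
    stopf("edge list line %d has fewer than 2 fields", line_no[bad[1]])
  }
  a <- normalize_ids(vapply(parts, `[`, character(1), 1), normalize)
  b <- normalize_ids(vapply(parts, `[`, character(1), 2), normalize)
  w <- vapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) < 3) return(1)
    wi <- suppressWarnings(as.numeric(p[3]))
    if (is.na(wi)) stopf("unparseable weight '%s' on line %d", p[3], line_no[i])
    wi
  }, numeric(1))
  self <- a == b
  if (any(self)) {
    warnf("skipping %d self-pair(s) (e.g. '%s')", sum(self), a[self][1])
    a <- a[!self]; b <- b[!self]; w <- w[!self]
  }
  if (length(a) == 0) return(gene_network())
  gene_network(data.frame(from = a, to = b, weight = w),
               metadata = list(source = path))
}

#' Write a gene network as a headerless edge TSV
#'
#' Lines `gene_a<TAB>gene_b<TAB>weight`, the inverse of [read_edge_list()].
#' Isolated nodes are not representable in this format.
#'
#' @param net A [gene_network()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(
    data.frame(net$edges$from, net$edges$to,
               format(net$edges$weight, digits = 15, trim = TRUE, scientific = FALSE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a gene or module network for external graph tools
#'
#' Supported formats: `"graphml"` (via igraph, re-readable by Cytoscape,
#' Gephi, yEd), `"json"` (a plain dialect
#' `{nodes:[{id,module,label}], edges:[{source,target,weight}]}`), and
#' `"edge-tsv"`. Module networks keep their self-loops (within-module
#' aggregate weight) in every format. When a partition is attached to a
#' gene network, node attributes carry the module index, term label and a
#' color index.
#'
#' @param net A [gene_network()] or [collapse_modules()] result.
#' @param path Output path.
#' @param format One of `"graphml"`, `"json"`, `"edge-tsv"`.
#' @param partition Optional [detect_modules()] partition whose labels are
#'   attached to gene nodes.
#' @return Invisibly, `path`.
#' @export
export_network <- function(net, path, format = c("graphml", "json", "edge-tsv"),
                           partition = NULL) {
  if (!is.character(format) || !all(format %in% c("graphml", "json", "edge-tsv"))) {
    stopf("unknown export format '%s'; supported: graphml, json, edge-tsv",
          paste(setdiff(format, c("graphml", "json", "edge-tsv")), collapse = ", "))
  }
  format <- match.arg(format)
  n_nodes <- if (inherits(net, "module_network")) nrow(net$nodes) else length(net$nodes)
  if (is.null(n_nodes) || n_nodes == 0) stopf("refusing to export an empty network")
  if (inherits(net, "module_network")) {
    nodes <- data.frame(id = as.character(net$nodes$module),
                        module = net$nodes$module,
                        label = net$nodes$label,
                        n_genes = net$nodes$n_genes,
                        color = net$nodes$color,
                        stringsAsFactors = FALSE)
    edges <- data.frame(source = as.character(net$edges$from),
                        target = as.character(net$edges$to),
                        weight = net$edges$weight, stringsAsFactors = FALSE)
    loops <- which(net$self_loops > 0)
    if (length(loops) > 0) {
      edges <- rbind(edges, data.frame(
        source = as.character(net$nodes$module[loops]),
        target = as.character(net$nodes$module[loops]),
        weight = unname(net$self_loops[loops]), stringsAsFactors = FALSE))
    }
  } else if (inherits(net, "gene_network")) {
    nodes <- data.frame(id = net$nodes, module = NA_integer_,
                        label = NA_character_, stringsAsFactors = FALSE)
    if (!is.null(partition)) {
      idx <- partition$assignment[nodes$id]
      nodes$module <- unname(idx)
      nodes$label <- unname(module_label(partition, idx))
      nodes$color <- unname(partition$module_colors[idx])
    }
    edges <- data.frame(source = net$edges$from, target = net$edges$to,
                        weight = net$edges$weight, stringsAsFactors = FALSE)
  } else {
    stopf("export_network expects a gene_network or module_network")
  }
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "json") {
    jsonlite::write_json(list(nodes = nodes, edges = edges), path,
                         auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    utils::write.table(
      data.frame(edges$source, edges$target,
                 format(edges$weight, digits = 15, trim = TRUE, scientific = FALSE)),
      path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write a coexpression matrix as dense delimited text
#'
#' Gene ids appear as both header row and first column; undefined entries
#' (zero-variance genes) are written as `NA`.
#'
#' @param C A [coexpression()] matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_coexpression <- function(C, path) {
  tab <- data.frame(gene = rownames(C), as.data.frame(unclass(C)[, , drop = FALSE]),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(tab) <- c("gene", colnames(C))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
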