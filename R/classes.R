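# Domain containers: expression matrices, annotation dictionaries, gene
# networks. All are light S3 wrappers over base structures so they print,
# subset and serialize predictably.

#' Construct an expression matrix container
#'
#' A genes x cells nonnegative matrix with gene/cell identifiers and a
#' per-cell cluster label. This is the input to per-cluster coexpression.
#'
#' @param values Numeric matrix, genes in rows, cells in columns, all
#'   entries `>= 0`.
#' @param gene_ids Character vector of unique gene identifiers (row names).
#' @param cell_ids Character vector of unique cell identifiers (column names).
#' @param cluster_labels Character vector, one cluster label per cell.
#'   Defaults to a single cluster `"all"`.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `gene_ids`, `cell_ids`, `cluster_labels`.
#' @examples
#' m <- matrix(0:5, nrow = 3)
#' expression_matrix(m, c("A", "B", "C"), c("c1", "c2"))
#' @export
expression_matrix <- function(values, gene_ids, cell_ids,
                              cluster_labels = rep("all", ncol(values))) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  cluster_labels <- as.character(cluster_labels)
  if (nrow(values) != length(gene_ids)) {
    stopf("gene_ids length (%d) != row count (%d)", length(gene_ids), nrow(values))
  }
  if (ncol(values) != length(cell_ids)) {
    stopf("cell_ids length (%d) != column count (%d)", length(cell_ids), ncol(values))
  }
  if (length(cluster_labels) != length(cell_ids)) {
    stopf("cluster_labels length (%d) != cell count (%d)",
          length(cluster_labels), length(cell_ids))
  }
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stopf("negative expression value at gene '%s', cell '%s'",
          gene_ids[neg[1, 1]], cell_ids[neg[1, 2]])
  }
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup) > 0) {
    stopf("duplicate gene ids: %s", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(cell_ids)) stopf("duplicate cell ids")
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 cluster_labels = cluster_labels),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d cells, %d cluster(s)\n",
              length(x$gene_ids), length(x$cell_ids),
              length(unique(x$cluster_labels))))
  invisible(x)
}

#' Subset an expression matrix to the cells of one cluster
#'
#' @param expr An [expression_matrix()].
#' @param cluster Cluster label to keep.
#' @return An `expression_matrix` restricted to the matching cells.
#' @export
subset_cluster <- function(expr, cluster) {
  keep <- expr$cluster_labels == cluster
  if (!any(keep)) stopf("no cells with cluster label '%s'", cluster)
  expression_matrix(expr$values[, keep, drop = FALSE], expr$gene_ids,
                    expr$cell_ids[keep], expr$cluster_labels[keep])
}

#' Construct an annotation dictionary (term -> gene set)
#'
#' Flattened gene-set annotations (GO terms, Reactome pathways, ...) used
#' to label modules. Terms arrive pre-flattened; no ontology parsing.
#'
#' @param sets Named list of character vectors; names are term ids, values
#'   the (nonempty) gene sets. Duplicate genes within a set are dropped.
#' @param labels Optional named character vector of human-readable term
#'   descriptions; defaults to the term ids.
#' @return An object of class `annotation_dictionary` with elements `sets`,
#'   `labels` and `universe` (all genes appearing in any term).
#' @examples
#' annotation_dictionary(list(T1 = c("A", "B"), T2 = c("B", "C")))
#' @export
annotation_dictionary <- function(sets, labels = NULL) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stopf("every term must be named")
  }
  if (anyDuplicated(names(sets))) {
    stopf("duplicate term ids: %s",
          paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty) > 0) {
    stopf("empty gene set for term(s): %s", paste(empty, collapse = ", "))
  }
  if (is.null(labels)) {
    labels <- stats::setNames(names(sets), names(sets))
  } else {
    labels <- stats::setNames(as.character(labels[names(sets)]), names(sets))
    labels[is.na(labels)] <- names(sets)[is.na(labels)]
  }
  structure(list(sets = sets, labels = labels,
                 universe = unique(unlist(sets, use.names = FALSE))),
            class = "annotation_dictionary")
}

#' @export
print.annotation_dictionary <- function(x, ...) {
  cat(sprintf("<annotation_dictionary> %d terms, %d genes in universe\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Construct an undirected weighted gene network
#'
#' Edges are canonicalized to unordered pairs (first endpoint sorts before
#' the second); duplicates keep the first occurrence and self-loops are
#' rejected. Nodes may include isolated genes when given explicitly.
#'
#' @param edges Data frame with columns `from`, `to` and optionally
#'   `weight` (default 1).
#' @param nodes Optional character vector of node ids; defaults to the
#'   union of edge endpoints.
#' @param metadata Named list recording how the network was extracted
#'   (metric, thinning strategy, parameters).
#' @return An object of class `gene_network` with elements `nodes`,
#'   `edges` (data frame `from`, `to`, `weight`) and `metadata`.
#' @examples
#' gene_network(data.frame(from = "B", to = "A", weight = 0.9))
#' @export
gene_network <- function(edges = NULL, nodes = NULL, metadata = list()) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!all(c("from", "to") %in% names(edges))) {
      stopf("edges must have columns 'from' and 'to'")
    }
    if (is.null(edges$weight)) edges$weight <- 1
    from <- as.character(edges$from)
    to <- as.character(edges$to)
    if (any(from == to)) stopf("self-loop edge on '%s'", from[from == to][1])
    a <- pmin(from, to)
    b <- pmax(from, to)
    edges <- data.frame(from = a, to = b, weight = as.numeric(edges$weight),
                        stringsAsFactors = FALSE)
    key <- paste(a, b, sep = "\r")
    if (anyDuplicated(key)) {
      first <- !duplicated(key)
      w_by_key <- split(edges$weight, key)
      conflicting <- vapply(w_by_key, function(w) length(unique(w)) > 1, logical(1))
      if (any(conflicting)) {
        warnf("%d duplicate edge pair(s) with conflicting weights; keeping the first occurrence",
              sum(conflicting))
      }
      edges <- edges[first, , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  endpoint_nodes <- unique(c(edges$from, edges$to))
  if (is.null(nodes)) {
    nodes <- endpoint_nodes
  } else {
    nodes <- unique(as.character(nodes))
    missing <- setdiff(endpoint_nodes, nodes)
    if (length(missing) > 0) {
      stopf("edge endpoint(s) not in nodes: %s", paste(missing, collapse = ", "))
    }
  }
  structure(list(nodes = nodes, edges = edges, metadata = metadata),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %d nodes, %d edges", length(x$nodes), nrow(x$edges)))
  if (!is.null(x$metadata$method)) cat(sprintf(" [%s]", x$metadata$method))
  cat("\n")
  invisible(x)
}

#' Number of edges of a gene network
#' @param net A [gene_network()].
#' @return Integer edge count.
#' @export
n_edges <- function(net) nrow(net$edges)

#' Convert a gene network to an igraph object
#'
#' @param net A [gene_network()].
#' @return An undirected `igraph` graph with a `weight` edge attribute;
#'   isolated nodes are preserved.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  g
}

#' Convert an igraph object to a gene network
#' @noRd
from_igraph <- function(g, metadata = list()) {
  ed <- igraph::as_data_frame(g, what = "edges")
  w <- if ("weight" %in% names(ed)) ed$weight else rep(1, nrow(ed))
  gene_network(data.frame(from = ed$from, to = ed$to, weight = w),
               nodes = igraph::V(g)$name, metadata = metadata)
}

#' Per-node degree of a gene network
#' @noRd
network_degrees <- function(net) {
  d <- stats::setNames(integer(length(net$nodes)), net$nodes)
  if (nrow(net$edges) > 0) {
    tab <- table(c(net$edges$from, net$edges$to))
    d[names(tab)] <- as.integer(tab)
  }
  d
}
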