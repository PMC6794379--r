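# Collapse a partitioned gene network into the module-module network.
# Every gene edge contributes its |weight| either to the edge between the
# two endpoint modules or, when internal, to that module's self-loop; the
# total aggregated weight is conserved.

#' Collapse a partitioned gene network into a module-module network
#'
#' Nodes are the partition's modules (with term labels, member counts and
#' a color index assigned by descending member count); the edge between
#' modules `g` and `h` aggregates the `|weight|` of all gene edges with
#' one endpoint in each, and each module's self-loop aggregates its
#' internal edges. With `mode = "mean"` aggregates are averaged instead of
#' summed (conservation then no longer holds; the sum is the default
#' because it preserves total interaction weight).
#'
#' @param net A [gene_network()].
#' @param part A [detect_modules()] partition covering `net`'s nodes.
#' @param mode `"sum"` (default) or `"mean"` aggregation.
#' @return An object of class `module_network`: `nodes` (data frame
#'   `module`, `term_id`, `label`, `n_genes`, `color`), `edges` (module
#'   pairs `from`, `to`, `weight`), `self_loops` (named numeric, one per
#'   module).
#' @export
collapse_modules <- function(net, part, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  mem <- partition_membership(part)
  missing <- setdiff(net$nodes, names(mem))
  if (length(missing) > 0) stopf("partition does not cover gene '%s'", missing[1])
  H <- part$H %||% length(unique(mem))
  mf <- unname(mem[net$edges$from])
  mt <- unname(mem[net$edges$to])
  w <- abs(net$edges$weight)
  a <- pmin(mf, mt)
  b <- pmax(mf, mt)
  internal <- a == b
  self_loops <- stats::setNames(numeric(H), seq_len(H))
  if (any(internal)) {
    agg <- tapply(w[internal], a[internal], if (mode == "sum") sum else mean)
    self_loops[names(agg)] <- as.numeric(agg)
  }
  if (any(!internal)) {
    key <- paste(a[!internal], b[!internal], sep = "|")
    agg <- tapply(w[!internal], key, if (mode == "sum") sum else mean)
    parts <- strsplit(names(agg), "|", fixed = TRUE)
    edges <- data.frame(
      from = as.integer(vapply(parts, `[`, character(1), 1)),
      to = as.integer(vapply(parts, `[`, character(1), 2)),
      weight = as.numeric(agg))
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = integer(), to = integer(), weight = numeric())
  }
  sizes <- tabulate(unname(mem[net$nodes]), H)
  terms <- if (!is.null(part$module_terms)) part$module_terms else rep(NA_character_, H)
  labels <- if (!is.null(part$module_labels)) part$module_labels else rep(UNLABELED, H)
  colors <- integer(H)
  colors[order(-sizes, seq_len(H))] <- seq_len(H)
  nodes <- data.frame(module = seq_len(H), term_id = terms, label = labels,
                      n_genes = sizes, color = colors, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, self_loops = self_loops,
                 mode = mode),
            class = "module_network")
}

#' @export
print.module_network <- function(x, ...) {
  cat(sprintf("<module_network> %d modules, %d cross edges, total weight %.4g\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$weight) + sum(x$self_loops)))
  invisible(x)
}

#' Per-module gene lists with term labels
#'
#' @param part A [detect_modules()] partition.
#' @return A list of data frames (one per module, named by module index),
#'   each with columns `gene`, `module`, `term_id`, `term_label`. Lists
#'   are disjoint and their union covers every partitioned gene;
#'   unlabeled modules carry the `"unlabeled"` sentinel.
#' @export
module_gene_lists <- function(part) {
  mem <- part$assignment
  lapply(stats::setNames(seq_len(part$H), seq_len(part$H)), function(h) {
    genes <- sort(names(mem)[mem == h])
    data.frame(gene = genes, module = h,
               term_id = part$module_terms[h] %|NA|% UNLABELED,
               term_label = module_label(part, h),
               stringsAsFactors = FALSE)
  })
}

#' @noRd
`%|NA|%` <- function(a, b) ifelse(is.na(a), b, a)

#' Write the gene -> module -> term table
#'
#' One row per gene: `gene`, `module`, `term_id`, `term_label` (TSV with a
#' header). The inverse of [read_module_table()].
#'
#' @param part A [detect_modules()] partition.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_module_table <- function(part, path) {
  tab <- do.call(rbind, module_gene_lists(part))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene -> module -> term table written by [write_module_table()]
#'
#' @param path Path to the TSV.
#' @return A `gene_partition` (without trajectory).
#' @export
read_module_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  mods <- sort(unique(tab$module))
  terms <- vapply(mods, function(h) tab$term_id[tab$module == h][1], character(1))
  labels <- vapply(mods, function(h) tab$term_label[tab$module == h][1], character(1))
  terms[terms == UNLABELED] <- NA_character_
  sizes <- as.integer(table(factor(tab$module, levels = mods)))
  colors <- integer(length(mods))
  colors[order(-sizes, seq_along(mods))] <- seq_along(mods)
  structure(list(assignment = stats::setNames(match(tab$module, mods), tab$gene),
                 module_terms = terms, module_labels = labels,
                 H = length(mods), module_sizes = sizes, module_colors = colors,
                 trajectory = data.frame(iteration = integer(), Q = numeric(),
                                         QGO = numeric()),
                 converged = NA, params = list()),
            class = "gene_partition")
}
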