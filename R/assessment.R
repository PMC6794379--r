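# Benchmarking extracted networks against a ground-truth network (GTN):
# affinity score, degree-preserving rewiring null, permutation p-value,
# method ranking, clustering coherence between runs, and the
# hypergeometric literature-consistency statistic.

#' Count homologous edges of two networks
#'
#' Homologous edges are unordered gene pairs present (with any weight) in
#' both edge sets; gene ids are compared after the readers' normalization.
#'
#' @param net,gtn [gene_network()] objects.
#' @return Integer count of shared unordered pairs.
#' @export
homologous_edges <- function(net, gtn) {
  if (n_edges(net) == 0 || n_edges(gtn) == 0) return(0L)
  length(intersect(edge_keys(net$edges$from, net$edges$to),
                   edge_keys(gtn$edges$from, gtn$edges$to)))
}

#' Affinity score between an extracted network and a ground truth
#'
#' `AS = h^2 / (n_edges(net) * n_edges(gtn))` where `h` is the homologous
#' edge count. Ranges in `[0, 1]`; 1 iff the edge sets coincide, 0 when no
#' edge is shared. Symmetric in its arguments.
#'
#' @param net,gtn Nonempty [gene_network()] objects.
#' @return Scalar affinity score.
#' @export
affinity_score <- function(net, gtn) {
  ne <- n_edges(net); ng <- n_edges(gtn)
  if (ne == 0 || ng == 0) stopf("affinity score requires both networks to have edges")
  h <- homologous_edges(net, gtn)
  h^2 / (ne * ng)
}

#' Degree-preserving rewiring of a network
#'
#' Randomizes edge identities via repeated double-edge swaps while keeping
#' the node set and per-node degree sequence exactly; swaps that would
#' create a self-loop or duplicate edge are rejected. This is the null
#' model behind [as_pvalue()]. Rewired edges carry weight 1 (the original
#' weight pairing is meaningless after swapping).
#'
#' @param net A [gene_network()] with at least 2 edges (otherwise returned
#'   unchanged with a warning; no valid swap exists).
#' @param n_swap_multiplier Attempted swaps = `multiplier * n_edges`
#'   (default 10).
#' @param seed Integer seed; the caller's RNG state is untouched.
#' @return A rewired [gene_network()] with identical nodes and degrees.
#' @export
rewire_network <- function(net, n_swap_multiplier = 10, seed = NULL) {
  m <- n_edges(net)
  if (m < 2) {
    warnf("network with %d edge(s) admits no degree-preserving swap; returned unchanged", m)
    return(net)
  }
  g <- as_igraph(net)
  niter <- ceiling(n_swap_multiplier * m)
  g2 <- with_seed(seed, igraph::rewire(
    g, igraph::keeping_degseq(loops = FALSE, niter = niter)))
  ed <- igraph::as_data_frame(g2, what = "edges")
  out <- gene_network(data.frame(from = ed$from, to = ed$to, weight = 1),
                      nodes = net$nodes,
                      metadata = c(net$metadata,
                                   list(rewired = TRUE, seed = seed,
                                        n_swap_multiplier = n_swap_multiplier)))
  stopifnot(identical(network_degrees(out)[net$nodes],
                      network_degrees(net)[net$nodes]))
  out
}

#' Permutation p-value for the affinity of a network to a ground truth
#'
#' Generates `n_perm` degree-preserving rewirings of `net`, recomputes the
#' affinity score of each against the GTN, and reports the add-one
#' permutation p-value `(1 + #{AS_rewired >= AS_observed}) / (1 + n_perm)`
#' (ties count toward the numerator; the estimator is never 0 and never
#' exceeds 1).
#'
#' @param net,gtn Nonempty [gene_network()] objects.
#' @param n_perm Number of rewired replicates (>= 19; default 100).
#' @param seed Integer seed; replicate `i` uses `seed + i`.
#' @param n_swap_multiplier Passed to [rewire_network()].
#' @return An object of class `assessment_result`: list with `method_id`,
#'   `affinity`, `p_value`, `n_permutations`, `seed`.
#' @export
as_pvalue <- function(net, gtn, n_perm = 100, seed = 1, n_swap_multiplier = 10) {
  if (n_perm < 19) stopf("n_perm must be >= 19")
  as_obs <- affinity_score(net, gtn)
  n_ge <- 0L
  for (i in seq_len(n_perm)) {
    ri <- rewire_network(net, n_swap_multiplier,
                         seed = (seed + i) %% .Machine$integer.max)
    if (affinity_score(ri, gtn) >= as_obs) n_ge <- n_ge + 1L
  }
  structure(list(method_id = net$metadata$method %||% "unknown",
                 affinity = as_obs,
                 p_value = (1 + n_ge) / (1 + n_perm),
                 n_permutations = n_perm, seed = seed),
            class = "assessment_result")
}

#' @export
print.assessment_result <- function(x, ...) {
  cat(sprintf("<assessment_result> %s: AS=%.4g, p=%.4g (%d permutations, seed %s)\n",
              x$method_id, x$affinity, x$p_value, x$n_permutations,
              format(x$seed)))
  invisible(x)
}

#' Rank extraction methods per cell type by -log(p)
#'
#' Builds the cell-type x method score matrix `-log(p_value)`, rescales it
#' min-max within each row to `[0, 1]` (a degenerate row — one method, or
#' all scores equal — rescales to 1 by convention), and flags the best
#' method(s) per row. The rescaled matrix is what a heatmap of method
#' performance should display.
#'
#' @param results Data frame with columns `cell_type`, `method`,
#'   `p_value` (all > 0), e.g. rows built from [as_pvalue()] results.
#' @return An object of class `method_ranking`: list with `scores`
#'   (`-log(p)` matrix), `rescaled` (per-row min-max), and `best_per_row`
#'   (named list; ties keep all tied method ids).
#' @export
rank_methods <- function(results) {
  results <- as.data.frame(results)
  need <- c("cell_type", "method", "p_value")
  if (!all(need %in% names(results))) {
    stopf("results must have columns %s", paste(need, collapse = ", "))
  }
  if (any(results$p_value <= 0)) stopf("all p-values must be > 0")
  rows <- unique(as.character(results$cell_type))
  cols <- unique(as.character(results$method))
  scores <- matrix(NA_real_, length(rows), length(cols),
                   dimnames = list(rows, cols))
  scores[cbind(match(results$cell_type, rows), match(results$method, cols))] <-
    -log(results$p_value)
  rescaled <- t(apply(scores, 1, function(r) {
    rng <- range(r, na.rm = TRUE)
    if (!is.finite(rng[1]) || rng[2] == rng[1]) {
      ifelse(is.na(r), NA_real_, 1)
    } else {
      (r - rng[1]) / (rng[2] - rng[1])
    }
  }))
  dimnames(rescaled) <- dimnames(scores)
  best <- lapply(rows, function(rt) {
    r <- scores[rt, ]
    cols[which(!is.na(r) & r == max(r, na.rm = TRUE))]
  })
  names(best) <- rows
  structure(list(scores = scores, rescaled = rescaled, best_per_row = best),
            class = "method_ranking")
}

#' @export
print.method_ranking <- function(x, ...) {
  cat(sprintf("<method_ranking> %d cell type(s) x %d method(s)\n",
              nrow(x$scores), ncol(x$scores)))
  for (rt in rownames(x$scores)) {
    cat(sprintf("  %s: best = %s\n", rt,
                paste(x$best_per_row[[rt]], collapse = ", ")))
  }
  invisible(x)
}

#' Clustering coherence of two module partitions
#'
#' Fraction of genes that end up with the same module label (annotation
#' term id) in two independently extracted and partitioned networks:
#' shared genes whose assigned term is identical (and not the unlabeled
#' sentinel), divided by the average gene count of the two networks.
#' Capped at 1.
#'
#' @param part_a,part_b [detect_modules()] partitions.
#' @return Scalar in `[0, 1]`.
#' @export
clustering_coherence <- function(part_a, part_b) {
  ga <- names(part_a$assignment)
  gb <- names(part_b$assignment)
  if (length(ga) == 0 || length(gb) == 0) stopf("both partitions must be nonempty")
  shared <- intersect(ga, gb)
  ta <- part_a$module_terms[part_a$assignment[shared]]
  tb <- part_b$module_terms[part_b$assignment[shared]]
  same <- sum(!is.na(ta) & !is.na(tb) & ta == tb)
  min(1, same / ((length(ga) + length(gb)) / 2))
}

#' Hypergeometric test of literature co-occurrence
#'
#' Upper-tail hypergeometric probability that, among `total_papers`
#' publications, a search combining a cell type (drawing `hits_celltype`
#' papers) and a pathway (`hits_pathway` papers marked as successes) would
#' share at least `hits_both` papers by chance: `P(X >= hits_both)`.
#'
#' @param hits_both Papers matching both queries.
#' @param hits_celltype Papers matching the cell-type query (draws).
#' @param hits_pathway Papers matching the pathway query (successes).
#' @param total_papers Population size.
#' @return Upper-tail p-value.
#' @export
hypergeom_literature <- function(hits_both, hits_celltype, hits_pathway,
                                 total_papers) {
  if (hits_both > min(hits_celltype, hits_pathway) ||
      max(hits_celltype, hits_pathway) > total_papers ||
      min(hits_both, hits_celltype, hits_pathway, total_papers) < 0) {
    stopf("inconsistent counts: need hits_both <= min(hits_celltype, hits_pathway) <= total_papers")
  }
  stats::phyper(hits_both - 1, hits_pathway, total_papers - hits_pathway,
                hits_celltype, lower.tail = FALSE)
}
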