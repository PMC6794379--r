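# Independent oracles and small fixture builders used across tests.
# These deliberately re-derive quantities longhand (set arithmetic, direct
# formulas, exhaustive enumeration) rather than calling package internals.

# All set partitions of n elements as restricted-growth strings.
set_partitions <- function(n) {
  res <- vector("list", 0)
  rgs <- integer(n)
  recurse <- function(i, maxv) {
    if (i > n) {
      res[[length(res) + 1]] <<- rgs
      return(invisible(NULL))
    }
    for (v in seq_len(maxv + 1)) {
      rgs[i] <<- v
      recurse(i + 1, max(maxv, v))
    }
  }
  recurse(1, 0)
  res
}

# Longhand modularity: sum over modules of e_h/|E| - (d_h / 2|E|)^2.
oracle_modularity <- function(mem, net) {
  nodes <- net$nodes
  m <- nrow(net$edges)
  deg <- setNames(numeric(length(nodes)), nodes)
  for (i in seq_len(m)) {
    deg[net$edges$from[i]] <- deg[net$edges$from[i]] + 1
    deg[net$edges$to[i]] <- deg[net$edges$to[i]] + 1
  }
  q <- 0
  for (h in unique(mem)) {
    members <- nodes[mem == h]
    e_h <- sum(net$edges$from %in% members & net$edges$to %in% members)
    d_h <- sum(deg[members])
    q <- q + e_h / m - (d_h / (2 * m))^2
  }
  q
}

# Longhand QGO with the stated term-selection rule (max overlap, ties to
# the smaller set then lexicographic id), normalized by annotated nodes.
oracle_qgo <- function(mem, net, dict) {
  nodes <- net$nodes
  n_annso <- sum(vapply(nodes, function(g) {
    any(vapply(dict$sets, function(s) g %in% s, logical(1)))
  }, logical(1)))
  total <- 0
  for (h in unique(mem)) {
    members <- nodes[mem == h]
    ov <- vapply(dict$sets, function(s) length(intersect(s, members)), integer(1))
    if (max(ov) == 0) next
    ord <- order(-ov, lengths(dict$sets), names(dict$sets))
    best <- names(dict$sets)[ord[1]]
    total <- total + length(intersect(dict$sets[[best]], members))
  }
  total / n_annso
}

# Two 4-cliques; optionally joined by one bridge edge (A1-B1).
two_clique_network <- function(bridge = TRUE) {
  clique_edges <- function(nodes) {
    idx <- t(combn(nodes, 2))
    data.frame(from = idx[, 1], to = idx[, 2], weight = 1,
               stringsAsFactors = FALSE)
  }
  a <- paste0("A", 1:4)
  b <- paste0("B", 1:4)
  edges <- rbind(clique_edges(a), clique_edges(b))
  if (bridge) edges <- rbind(edges, data.frame(from = "A1", to = "B1", weight = 1))
  gene_network(edges, nodes = c(a, b))
}

# Inverse-CDF sampler from the discrete power law P(k) ~ k^-gamma, k >= 1.
sample_power_law_degrees <- function(n, gamma, seed, kmax = 100000L) {
  set.seed(seed)
  p <- (seq_len(kmax))^(-gamma)
  cdf <- cumsum(p / sum(p))
  findInterval(runif(n), cdf) + 1L
}

# Wrap a symmetric weight matrix as a coexpression_matrix for thinning tests.
fake_coexpression <- function(mat, metric = "pearson") {
  diag(mat) <- NA_real_
  structure(mat, metric = metric, n_cells = NA_integer_,
            class = c("coexpression_matrix", "matrix"))
}

# Coexpression-matrix shell holding 0 everywhere except the given edges.
coexpr_from_edges <- function(nodes, edges, weight_col = "weight") {
  mat <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    mat[edges$from[i], edges$to[i]] <- edges[[weight_col]][i]
    mat[edges$to[i], edges$from[i]] <- edges[[weight_col]][i]
  }
  fake_coexpression(mat)
}

# Random gene network on n nodes (Erdos-Renyi), named G1..Gn.
random_network <- function(n, p, seed) {
  set.seed(seed)
  nodes <- paste0("G", seq_len(n))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  hit <- runif(nrow(idx)) < p
  gene_network(data.frame(from = nodes[idx[hit, 1]], to = nodes[idx[hit, 2]],
                          weight = 1),
               nodes = nodes)
}
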