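# Seed-deterministic synthetic generators with planted structure. These
# define the study conditions every stage is tested under: stochastic
# block models for networks, a log-normal latent-factor model for
# expression counts, block-derived annotation dictionaries, and
# configuration-model power-law networks.

#' @noRd
planted_truth <- function(block_assignment, block_terms, params) {
  structure(list(block_assignment = block_assignment,
                 block_terms = block_terms, params = params),
            class = "planted_truth")
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf("<planted_truth> %d genes in %d blocks\n",
              length(x$block_assignment), length(x$block_terms)))
  invisible(x)
}

#' Serialize a planted truth next to its fixture
#'
#' @param truth A `planted_truth`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_planted_truth <- function(truth, path) {
  jsonlite::write_json(list(block_assignment = as.list(truth$block_assignment),
                            block_terms = as.list(truth$block_terms),
                            params = truth$params),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @noRd
block_gene_ids <- function(block_sizes) {
  sprintf("G%04d", seq_len(sum(block_sizes)))
}

#' Generate a stochastic-block-model gene network
#'
#' Within-block gene pairs connect with probability `p_in`, cross-block
#' pairs with `p_out < p_in`; all edges weigh 1. Genes are named `G0001`,
#' `G0002`, ... and all genes stay in the node set (isolated ones
#' included).
#'
#' @param block_sizes Integer vector of block sizes (each >= 2).
#' @param p_in,p_out Edge probabilities, `p_in > p_out`.
#' @param seed Integer seed.
#' @return List with `network` (a [gene_network()]) and `truth` (a
#'   `planted_truth` with `block_assignment`, `block_terms` `T1`, `T2`,
#'   ... and the generation parameters).
#' @export
gen_planted_network <- function(block_sizes, p_in, p_out, seed = 1) {
  if (any(block_sizes < 2)) stopf("all block sizes must be >= 2")
  if (p_in <= p_out) stopf("p_in must exceed p_out")
  genes <- block_gene_ids(block_sizes)
  n <- length(genes)
  block <- rep(seq_along(block_sizes), block_sizes)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  p <- ifelse(block[idx[, 1]] == block[idx[, 2]], p_in, p_out)
  hit <- with_seed(seed, stats::runif(nrow(idx)) < p)
  edges <- data.frame(from = genes[idx[hit, 1]], to = genes[idx[hit, 2]],
                      weight = 1)
  net <- gene_network(edges, nodes = genes,
                      metadata = list(method = "planted_sbm", p_in = p_in,
                                      p_out = p_out, seed = seed))
  truth <- planted_truth(stats::setNames(block, genes),
                         stats::setNames(paste0("T", seq_along(block_sizes)),
                                         seq_along(block_sizes)),
                         list(block_sizes = block_sizes, p_in = p_in,
                              p_out = p_out, seed = seed))
  list(network = net, truth = truth)
}

#' Generate a planted-block expression matrix
#'
#' Log-normal latent-factor model emulating normalized single-cell
#' counts: genes of one block share a per-cell latent factor, so
#' `log` expression is `mu_g + sqrt(base_corr) * z[block, cell] +
#' noise_sd * eps`, exponentiated and rounded to nonnegative integers.
#' The within-block correlation of the latent log scale is
#' `base_corr / (base_corr + noise_sd^2)`, so `noise_sd -> 0` gives a
#' deterministic monotone map (within-block Spearman -> 1) while
#' cross-block factors stay independent. Dropout is emulated by zeroing
#' entries below the `dropout_rate` quantile.
#'
#' @param block_sizes Integer vector of block sizes.
#' @param n_cells Number of cells (>= 10).
#' @param base_corr Latent-factor strength in `(0, 1)`.
#' @param noise_sd Gene-level log-normal noise SD (> 0 in practice; 0 is
#'   allowed for limiting-case checks).
#' @param dropout_rate Fraction of entries zeroed from the bottom of the
#'   value distribution (default 0.3).
#' @param seed Integer seed.
#' @return List with `expression` (an [expression_matrix()], one cluster
#'   `"cluster1"`) and `truth`.
#' @export
gen_planted_expression <- function(block_sizes, n_cells = 200, base_corr = 0.8,
                                   noise_sd = 0.3, dropout_rate = 0.3,
                                   seed = 1) {
  if (n_cells < 10) stopf("n_cells must be >= 10")
  if (base_corr <= 0 || base_corr >= 1) stopf("base_corr must be in (0, 1)")
  genes <- block_gene_ids(block_sizes)
  n <- length(genes)
  block <- rep(seq_along(block_sizes), block_sizes)
  values <- with_seed(seed, {
    z <- matrix(stats::rnorm(length(block_sizes) * n_cells),
                length(block_sizes), n_cells)
    mu <- stats::runif(n, 1, 3)
    logx <- mu + sqrt(base_corr) * z[block, , drop = FALSE] +
      noise_sd * matrix(stats::rnorm(n * n_cells), n, n_cells)
    v <- round(exp(logx))
    if (dropout_rate > 0) {
      thresh <- stats::quantile(v, dropout_rate)
      v[v < thresh] <- 0
    }
    v
  })
  expr <- expression_matrix(values, genes, sprintf("CELL%04d", seq_len(n_cells)),
                            rep("cluster1", n_cells))
  truth <- planted_truth(stats::setNames(block, genes),
                         stats::setNames(paste0("T", seq_along(block_sizes)),
                                         seq_along(block_sizes)),
                         list(block_sizes = block_sizes, n_cells = n_cells,
                              base_corr = base_corr, noise_sd = noise_sd,
                              dropout_rate = dropout_rate, seed = seed))
  list(expression = expr, truth = truth)
}

#' Generate an annotation dictionary from a planted truth
#'
#' One term per block (`T1`, `T2`, ...): a `coverage` fraction of the
#' block's genes plus foreign genes from other blocks so that the
#' contaminated fraction of the final set is `contamination`. Optional
#' decoy terms draw random genes and match no block.
#'
#' @param truth A `planted_truth` from the generators above.
#' @param coverage Fraction of each block sampled into its term, `(0, 1]`.
#' @param contamination Foreign-gene fraction of each term, `[0, 1)`.
#' @param n_decoys Number of decoy terms (default 0).
#' @param seed Integer seed.
#' @return An [annotation_dictionary()].
#' @export
gen_annotation_dict <- function(truth, coverage = 1, contamination = 0,
                                n_decoys = 0, seed = 1) {
  if (coverage <= 0 || coverage > 1) stopf("coverage must be in (0, 1]")
  if (contamination < 0 || contamination >= 1) stopf("contamination must be in [0, 1)")
  block <- truth$block_assignment
  genes <- names(block)
  with_seed(seed, {
    sets <- list()
    labels <- character(0)
    for (b in sort(unique(block))) {
      own_pool <- genes[block == b]
      n_own <- max(1, round(coverage * length(own_pool)))
      own <- sort(sample(own_pool, n_own))
      n_foreign <- round(n_own * contamination / (1 - contamination))
      foreign <- if (n_foreign > 0) {
        sample(genes[block != b], min(n_foreign, sum(block != b)))
      } else character(0)
      id <- truth$block_terms[[as.character(b)]]
      sets[[id]] <- c(own, foreign)
      labels[id] <- sprintf("Block %s program", b)
    }
    for (d in seq_len(n_decoys)) {
      id <- sprintf("DECOY%d", d)
      sets[[id]] <- sample(genes, max(2, round(stats::median(lengths(sets)))))
      labels[id] <- sprintf("Decoy set %d", d)
    }
    annotation_dictionary(sets, labels)
  })
}

#' Generate a power-law (scale-free) gene network
#'
#' Samples node degrees from the discrete power law `P(k) ~ k^-gamma`
#' (`k >= 1`) by inverse CDF, makes the degree sum even, wires a
#' configuration-model multigraph and simplifies it (no self-loops or
#' multi-edges). [fit_degree_power_law()] on the result's degrees recovers
#' `gamma` to within sampling error.
#'
#' @param n_nodes Number of genes (>= 100).
#' @param gamma Power-law exponent in `(2, 3.5)`.
#' @param seed Integer seed.
#' @return A [gene_network()] (all `n_nodes` genes in the node set; edges
#'   weigh 1).
#' @export
gen_power_law_network <- function(n_nodes, gamma = 2.5, seed = 1) {
  if (n_nodes < 100) stopf("n_nodes must be >= 100")
  if (gamma <= 2 || gamma >= 3.5) stopf("gamma must be in (2, 3.5)")
  genes <- sprintf("G%05d", seq_len(n_nodes))
  g <- with_seed(seed, {
    kmax <- n_nodes - 1L
    p <- (seq_len(kmax))^(-gamma)
    d <- sample.int(kmax, n_nodes, replace = TRUE, prob = p / sum(p))
    if (sum(d) %% 2 == 1) d[1] <- d[1] + 1L
    igraph::simplify(igraph::sample_degseq(d, method = "configuration"))
  })
  igraph::V(g)$name <- genes
  from_igraph(g, metadata = list(method = "power_law_configuration",
                                 gamma = gamma, seed = seed))
}
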