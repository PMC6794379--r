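# Network thinning: the coexpression matrix is a fully connected weighted
# network; these strategies keep only the informative edges. Weight
# magnitude |c| is the retention criterion for every metric; undefined
# (NA) entries never become edges. Isolated genes are dropped from the
# extracted network's node set (downstream modularity is undefined for
# degree-0 nodes).

#' @noRd
upper_pairs <- function(C) {
  genes <- rownames(C)
  idx <- which(upper.tri(C), arr.ind = TRUE)
  w <- C[idx]
  keep <- !is.na(w)
  list(from = genes[idx[keep, 1]], to = genes[idx[keep, 2]], weight = w[keep])
}

#' @noRd
network_from_pairs <- function(pairs, keep, metadata) {
  if (!any(keep)) return(gene_network(metadata = metadata))
  gene_network(data.frame(from = pairs$from[keep], to = pairs$to[keep],
                          weight = pairs$weight[keep], stringsAsFactors = FALSE),
               metadata = metadata)
}

#' Thin a coexpression network by absolute-value threshold
#'
#' Retains the edge between genes `i` and `k` iff `|c[i, k]| >= t` and the
#' entry is defined. Signed weights are preserved.
#'
#' @param C A [coexpression()] matrix.
#' @param t Nonnegative threshold.
#' @return A [gene_network()] whose metadata records the strategy.
#' @export
thin_abs_threshold <- function(C, t) {
  if (t < 0) stopf("threshold must be nonnegative")
  pairs <- upper_pairs(C)
  network_from_pairs(pairs, abs(pairs$weight) >= t,
                     list(method = paste0(attr(C, "metric"), "+abs_threshold"),
                          metric = attr(C, "metric"),
                          strategy = "abs_threshold", threshold = t))
}

#' Thin a coexpression network to the top percentile of |c|
#'
#' Keeps the edges whose absolute weight ranks in the top `q` percent of
#' all defined off-diagonal pairs. Ties at the boundary are all retained,
#' so at least `ceiling(q% * n_pairs)` edges survive.
#'
#' @param C A [coexpression()] matrix.
#' @param q Percentile in `(0, 100]`; `q = 100` keeps every defined pair.
#' @return A [gene_network()].
#' @export
thin_percentile <- function(C, q) {
  if (q <= 0 || q > 100) stopf("percentile must be in (0, 100]")
  pairs <- upper_pairs(C)
  metadata <- list(method = paste0(attr(C, "metric"), "+percentile", q),
                   metric = attr(C, "metric"),
                   strategy = "percentile", percentile = q)
  n <- length(pairs$weight)
  if (n == 0) return(gene_network(metadata = metadata))
  k <- ceiling(q / 100 * n)
  cutoff <- sort(abs(pairs$weight), decreasing = TRUE)[k]
  network_from_pairs(pairs, abs(pairs$weight) >= cutoff, metadata)
}

#' Fit a discrete power law to a degree distribution
#'
#' Maximum-likelihood fit of `P(k) ~ k^-gamma` with `x_min` fixed at 1,
#' scored by the Kolmogorov-Smirnov distance between the empirical and
#' fitted degree CDFs (smaller is better). Used by [thin_scale_free()] to
#' judge how scale-free a candidate subnetwork is.
#'
#' @param degrees Positive integer degree multiset.
#' @param cutoff Optional threshold to record alongside the fit.
#' @return An object of class `power_law_fit`: list with `gamma_hat`,
#'   `gof` (KS distance), `n_nodes`, `n_edges`, `cutoff`, and `defined`
#'   (FALSE when fewer than 3 distinct positive degrees are present, in
#'   which case `gamma_hat`/`gof` are `NA`).
#' @export
fit_degree_power_law <- function(degrees, cutoff = NA_real_) {
  degrees <- degrees[degrees > 0]
  n_nodes <- length(degrees)
  n_edges <- sum(degrees) / 2
  if (length(unique(degrees)) < 3) {
    return(structure(list(gamma_hat = NA_real_, gof = NA_real_,
                          n_nodes = n_nodes, n_edges = n_edges,
                          cutoff = cutoff, defined = FALSE),
                     class = "power_law_fit"))
  }
  fit <- igraph::fit_power_law(degrees, xmin = 1, implementation = "plfit")
  structure(list(gamma_hat = fit$alpha, gof = fit$KS.stat,
                 n_nodes = n_nodes, n_edges = n_edges,
                 cutoff = cutoff, defined = TRUE),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("<power_law_fit> gamma_hat=%.3f KS=%.4f (%d nodes, %d edges)\n",
                x$gamma_hat, x$gof, x$n_nodes, as.integer(x$n_edges)))
  } else {
    cat("<power_law_fit> undefined (fewer than 3 distinct positive degrees)\n")
  }
  invisible(x)
}

#' Thin a coexpression network toward a scale-free topology
#'
#' Grid search: for each cutoff, edges with `|c| < cutoff` are removed, a
#' discrete power law is fitted to the surviving degree distribution, and
#' the candidate is scored by `gof + |gamma_hat - gamma_target|` (KS fit
#' quality plus closeness of the exponent to the target, equal weight).
#' The cutoff minimizing the score wins; all per-cutoff fits are returned
#' so users can re-rank under their own criterion.
#'
#' @param C A [coexpression()] matrix.
#' @param cutoff_grid Ascending positive cutoffs to try.
#' @param gamma_target Target power-law exponent (default 2.5; biological
#'   networks typically show gamma in \[2, 3\]).
#' @return A list of class `scale_free_thinning`: `network` (the winning
#'   [gene_network()]), `fit` (its [fit_degree_power_law()]), and `log`, a
#'   data frame with one row per cutoff (cutoff, n_nodes, n_edges,
#'   gamma_hat, gof, score).
#' @export
thin_scale_free <- function(C, cutoff_grid, gamma_target = 2.5) {
  if (length(cutoff_grid) == 0) stopf("cutoff_grid must be nonempty")
  cutoff_grid <- sort(as.numeric(cutoff_grid))
  pairs <- upper_pairs(C)
  rows <- vector("list", length(cutoff_grid))
  nets <- vector("list", length(cutoff_grid))
  fits <- vector("list", length(cutoff_grid))
  for (i in seq_along(cutoff_grid)) {
    ct <- cutoff_grid[i]
    keep <- abs(pairs$weight) >= ct
    net <- network_from_pairs(pairs, keep,
      list(method = paste0(attr(C, "metric"), "+scale_free"),
           metric = attr(C, "metric"),
           strategy = "scale_free", cutoff = ct, gamma_target = gamma_target))
    fit <- fit_degree_power_law(network_degrees(net), cutoff = ct)
    nets[[i]] <- net
    fits[[i]] <- fit
    rows[[i]] <- data.frame(cutoff = ct, n_nodes = length(net$nodes),
                            n_edges = n_edges(net), gamma_hat = fit$gamma_hat,
                            gof = fit$gof,
                            score = if (fit$defined) {
                              fit$gof + abs(fit$gamma_hat - gamma_target)
                            } else NA_real_)
  }
  log_df <- do.call(rbind, rows)
  if (all(is.na(log_df$score))) {
    stopf("no cutoff in the grid yields a defined power-law fit; try a denser or lower grid")
  }
  best <- which.min(log_df$score)
  structure(list(network = nets[[best]], fit = fits[[best]], log = log_df),
            class = "scale_free_thinning")
}

#' @export
print.scale_free_thinning <- function(x, ...) {
  cat(sprintf("<scale_free_thinning> selected cutoff %.4g (gamma_hat=%.3f, KS=%.4f)\n",
              x$fit$cutoff, x$fit$gamma_hat, x$fit$gof))
  invisible(x)
}

#' Apply a thinning configuration to a coexpression matrix
#'
#' Dispatcher used by the pipeline: `strategy` selects one of
#' [thin_abs_threshold()], [thin_percentile()], [thin_scale_free()].
#'
#' @param C A [coexpression()] matrix.
#' @param strategy One of `"abs_threshold"`, `"percentile"`, `"scale_free"`.
#' @param threshold,percentile,cutoff_grid,gamma_target Strategy parameters.
#' @return A [gene_network()] (for `scale_free`, the winning network; the
#'   full fit log is attached as attribute `"thinning_log"`).
#' @export
thin_network <- function(C, strategy = c("percentile", "abs_threshold", "scale_free"),
                         threshold = 0.5, percentile = 20,
                         cutoff_grid = seq(0.2, 0.9, by = 0.1),
                         gamma_target = 2.5) {
  strategy <- match.arg(strategy)
  switch(strategy,
    abs_threshold = thin_abs_threshold(C, threshold),
    percentile = thin_percentile(C, percentile),
    scale_free = {
      res <- thin_scale_free(C, cutoff_grid, gamma_target)
      attr(res$network, "thinning_log") <- res$log
      res$network
    })
}
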