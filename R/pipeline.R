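# End-to-end per-cluster orchestration: QC filtering -> variable-gene
# selection -> coexpression -> thinning -> module detection -> collapse ->
# export, under a single seeded configuration with provenance logging.

#' Quality-control filter on cells
#'
#' Retains cells meeting all three criteria, evaluated jointly on the
#' input matrix: expressed-gene count `>= min_genes`, UMI total
#' `<= max_umi` (inclusive), and mitochondrial fraction
#' `<= max_mito_fraction`. Mitochondrial genes are recognized by id
#' prefix (after the readers' normalization both `"MT-"` and `"mt-"`
#' collapse to `"MT-"`). The defaults match common single-cell practice
#' for droplet data.
#'
#' @param expr An [expression_matrix()].
#' @param min_genes Minimum expressed (nonzero) genes per cell.
#' @param max_umi Maximum UMI total per cell.
#' @param max_mito_fraction Maximum mitochondrial fraction of the UMI
#'   total (a cell with zero UMIs counts as fraction 0).
#' @param mito_prefix Character vector of id prefixes marking
#'   mitochondrial genes.
#' @return The filtered `expression_matrix`; attribute `"qc_removed"`
#'   holds per-criterion removal counts (overlaps possible) and the total.
#' @export
qc_filter_cells <- function(expr, min_genes = 500, max_umi = 10000,
                            max_mito_fraction = 0.1,
                            mito_prefix = c("MT-", "MT.")) {
  x <- expr$values
  expressed <- colSums(x > 0)
  umi <- colSums(x)
  is_mito <- Reduce(`|`, lapply(toupper(mito_prefix),
                                function(p) startsWith(toupper(expr$gene_ids), p)))
  mito <- if (any(is_mito)) colSums(x[is_mito, , drop = FALSE]) else numeric(ncol(x))
  frac <- ifelse(umi > 0, mito / umi, 0)
  pass_genes <- expressed >= min_genes
  pass_umi <- umi <= max_umi
  pass_mito <- frac <= max_mito_fraction
  keep <- pass_genes & pass_umi & pass_mito
  removed <- c(low_genes = sum(!pass_genes), high_umi = sum(!pass_umi),
               high_mito = sum(!pass_mito), total = sum(!keep))
  if (!any(keep)) {
    stopf("no cell passes QC (removed: %d below %d genes, %d above %d UMIs, %d above mito fraction %g)",
          removed[["low_genes"]], min_genes, removed[["high_umi"]], max_umi,
          removed[["high_mito"]], max_mito_fraction)
  }
  out <- expression_matrix(x[, keep, drop = FALSE], expr$gene_ids,
                           expr$cell_ids[keep], expr$cluster_labels[keep])
  attr(out, "qc_removed") <- removed
  out
}

#' Drop cell clusters smaller than a minimum size
#'
#' Strict inequality: a cluster with exactly `min_cells` cells is kept.
#'
#' @param expr An [expression_matrix()].
#' @param min_cells Minimum cluster size (default 50).
#' @return The filtered `expression_matrix` (possibly with zero cells, in
#'   which case a warning is raised and downstream steps should abort).
#' @export
filter_small_clusters <- function(expr, min_cells = 50) {
  sizes <- table(expr$cluster_labels)
  keep_clusters <- names(sizes)[sizes >= min_cells]
  keep <- expr$cluster_labels %in% keep_clusters
  if (!any(keep)) {
    warnf("all clusters have fewer than %d cells; result is empty", min_cells)
  }
  expression_matrix(expr$values[, keep, drop = FALSE], expr$gene_ids,
                    expr$cell_ids[keep], expr$cluster_labels[keep])
}

#' Select highly variable genes by binned dispersion
#'
#' Ranks genes by their variance-to-mean dispersion standardized within
#' 20 mean-expression bins (so highly expressed genes do not dominate),
#' and returns the top `n_top` ids. Deterministic; ties break by gene id.
#'
#' @param expr An [expression_matrix()].
#' @param n_top Number of genes to return (`<=` gene count).
#' @param n_bins Number of mean-expression bins (default 20).
#' @return Character vector of `n_top` gene ids, ranked.
#' @export
select_variable_genes <- function(expr, n_top, n_bins = 20) {
  if (n_top > length(expr$gene_ids)) {
    stopf("n_top (%d) exceeds gene count (%d)", n_top, length(expr$gene_ids))
  }
  x <- expr$values
  mu <- rowMeans(x)
  v <- apply(x, 1, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- cut(mu, breaks = unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1))),
              include.lowest = TRUE)
  z <- stats::ave(disp, bins, FUN = function(d) {
    s <- stats::sd(d)
    if (is.na(s) || s == 0) rep(0, length(d)) else (d - mean(d)) / s
  })
  expr$gene_ids[order(-z, expr$gene_ids)][seq_len(n_top)]
}

#' Build a pipeline run configuration
#'
#' Collects input paths, QC thresholds, the coexpression metric, the
#' thinning configuration, module-detection parameters, and the master
#' seed for a [run_pipeline()] call. Defaults mirror common droplet
#' single-cell QC practice and the package's default extraction settings.
#'
#' @param expression_path Path to the expression matrix
#'   ([read_expression()] formats).
#' @param gmt_path Path to the annotation dictionary (GMT).
#' @param outdir Output directory (created if absent).
#' @param clusters_path Optional cluster-label file.
#' @param gtn_path Optional ground-truth edge list; when set, each
#'   cluster's extracted network is benchmarked via [as_pvalue()].
#' @param metric Coexpression metric (see [coexpression()]).
#' @param pseudocount Pseudocount for `rho`/`phi`.
#' @param thinning Named list: `strategy` plus its parameters (see
#'   [thin_network()]).
#' @param qc Named list of [qc_filter_cells()] thresholds: `min_genes`,
#'   `max_umi`, `max_mito_fraction`.
#' @param min_cluster_size Minimum cells per retained cluster.
#' @param n_top_genes Number of variable genes per cluster (`NULL` = all).
#' @param modules Named list of [detect_modules()] parameters: `T`,
#'   `max_iter`, `topology_weight`, `density_mode`.
#' @param n_perm Rewiring replicates for the optional assessment.
#' @param seed Master seed; cluster `i` runs under `seed + i`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(expression_path, gmt_path, outdir,
                       clusters_path = NULL, gtn_path = NULL,
                       metric = "spearman", pseudocount = 1,
                       thinning = list(strategy = "percentile", percentile = 20),
                       qc = list(min_genes = 500, max_umi = 10000,
                                 max_mito_fraction = 0.1),
                       min_cluster_size = 50, n_top_genes = NULL,
                       modules = list(T = 1e-4, max_iter = 200,
                                   topology_weight = 0.5, density_mode = FALSE),
                       n_perm = 100, seed = 1) {
  cfg <- list(expression_path = expression_path, gmt_path = gmt_path,
              outdir = outdir, clusters_path = clusters_path,
              gtn_path = gtn_path, metric = metric, pseudocount = pseudocount,
              thinning = thinning, qc = qc,
              min_cluster_size = min_cluster_size, n_top_genes = n_top_genes,
              modules = modules, n_perm = n_perm, seed = seed)
  class(cfg) <- "run_config"
  cfg
}

#' @noRd
config_hash <- function(cfg) {
  # identifies the analysis configuration, not the destination
  cfg <- unclass(cfg)
  cfg$outdir <- NULL
  rolling_hash(paste(deparse(cfg), collapse = "\n"))
}

#' Run the full per-cluster pipeline
#'
#' For every cluster surviving QC and the minimum-size filter:
#' variable-gene selection, coexpression under the configured metric,
#' thinning, module detection, and module collapse. Each cluster writes
#' `coexpression.tsv`, `network_edges.tsv`, `gene_modules.tsv`,
#' `trajectory.csv`, `module_network.graphml`, `module_network.json` and
#' a `manifest.tsv` naming every file with the config hash and cluster
#' seed, into `outdir/cluster_<label>/`. A run-level `run_log.txt`
#' records parameters, QC removal counts and per-cluster status. When a
#' GTN is configured, `assessment.tsv` (cluster, method, affinity, p,
#' seed) is written at the run level.
#'
#' A failing cluster is logged and skipped; the call errors only if every
#' cluster fails. Outputs are deterministic given the configuration and
#' seed.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a named list of per-cluster results (`network`,
#'   `partition`, `module_network`, optional `assessment`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  log_lines <- c(sprintf("config_hash: %s", hash),
                 sprintf("seed: %d", cfg$seed),
                 sprintf("metric: %s", cfg$metric),
                 sprintf("thinning: %s", paste(names(cfg$thinning),
                                               unlist(cfg$thinning),
                                               sep = "=", collapse = " ")))
  expr <- read_expression(cfg$expression_path, clusters_path = cfg$clusters_path)
  dict <- read_gmt(cfg$gmt_path)
  gtn <- if (!is.null(cfg$gtn_path)) read_edge_list(cfg$gtn_path) else NULL
  expr <- qc_filter_cells(expr, cfg$qc$min_genes, cfg$qc$max_umi,
                          cfg$qc$max_mito_fraction)
  qc_removed <- attr(expr, "qc_removed")
  log_lines <- c(log_lines,
                 sprintf("qc_removed: %s",
                         paste(names(qc_removed), qc_removed, sep = "=",
                               collapse = " ")))
  expr <- filter_small_clusters(expr, cfg$min_cluster_size)
  clusters <- sort(unique(expr$cluster_labels))
  if (length(clusters) == 0) stopf("no cluster survives filtering")
  results <- list()
  assessment_rows <- list()
  for (i in seq_along(clusters)) {
    cl <- clusters[i]
    cl_seed <- cfg$seed + i
    status <- tryCatch({
      res <- run_one_cluster(expr, cl, cl_seed, dict, gtn, cfg, hash)
      results[[cl]] <- res
      if (!is.null(res$assessment)) {
        assessment_rows[[cl]] <- data.frame(
          cluster = cl, method = res$assessment$method_id,
          affinity = res$assessment$affinity,
          p_value = res$assessment$p_value, seed = cl_seed)
      }
      sprintf("cluster %s: ok (%d genes, %d edges, %d modules, seed %d)",
              cl, length(res$network$nodes), n_edges(res$network),
              res$partition$H, cl_seed)
    }, error = function(e) {
      sprintf("cluster %s: FAILED (%s)", cl, conditionMessage(e))
    })
    log_lines <- c(log_lines, status)
  }
  if (length(results) == 0) {
    writeLines(log_lines, file.path(cfg$outdir, "run_log.txt"))
    stopf("all clusters failed; see %s", file.path(cfg$outdir, "run_log.txt"))
  }
  if (length(assessment_rows) > 0) {
    utils::write.table(do.call(rbind, assessment_rows),
                       file.path(cfg$outdir, "assessment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(log_lines, file.path(cfg$outdir, "run_log.txt"))
  invisible(results)
}

#' @noRd
run_one_cluster <- function(expr, cl, cl_seed, dict, gtn, cfg, hash) {
  sub <- subset_cluster(expr, cl)
  if (!is.null(cfg$n_top_genes)) {
    top <- select_variable_genes(sub, min(cfg$n_top_genes, length(sub$gene_ids)))
    sub <- expression_matrix(sub$values[top, , drop = FALSE], top,
                             sub$cell_ids, sub$cluster_labels)
  }
  C <- coexpression(sub, cfg$metric, pseudocount = cfg$pseudocount)
  net <- do.call(thin_network, c(list(C = C), cfg$thinning))
  if (n_edges(net) == 0) stopf("thinning left no edges")
  part <- detect_modules(net, dict, T = cfg$modules$T %||% 1e-4,
                         max_iter = cfg$modules$max_iter %||% 200,
                         seed = cl_seed,
                         topology_weight = cfg$modules$topology_weight %||% 0.5,
                         density_mode = isTRUE(cfg$modules$density_mode))
  modnet <- collapse_modules(net, part)
  cl_dir <- file.path(cfg$outdir, paste0("cluster_", gsub("[^A-Za-z0-9_.-]", "_", cl)))
  dir.create(cl_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(coexpression = "coexpression.tsv",
             edges = "network_edges.tsv",
             modules = "gene_modules.tsv",
             trajectory = "trajectory.csv",
             graphml = "module_network.graphml",
             json = "module_network.json")
  write_coexpression(C, file.path(cl_dir, files["coexpression"]))
  write_edge_list(net, file.path(cl_dir, files["edges"]))
  write_module_table(part, file.path(cl_dir, files["modules"]))
  utils::write.csv(part$trajectory, file.path(cl_dir, files["trajectory"]),
                   row.names = FALSE)
  export_network(modnet, file.path(cl_dir, files["graphml"]), "graphml")
  export_network(modnet, file.path(cl_dir, files["json"]), "json")
  utils::write.table(
    data.frame(file = unname(files), config_hash = hash, seed = cl_seed),
    file.path(cl_dir, "manifest.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  assessment <- NULL
  if (!is.null(gtn) && n_edges(gtn) > 0) {
    assessment <- as_pvalue(net, gtn, n_perm = cfg$n_perm, seed = cl_seed)
  }
  list(network = net, partition = part, module_network = modnet,
       coexpression = C, assessment = assessment)
}
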