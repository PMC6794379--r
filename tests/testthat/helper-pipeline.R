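# Pipeline fixtures shared by the pipeline and acceptance tests.

make_qc_fixture <- function() {
  # 100 cells: 93 clean, 7 violating exactly one criterion each.
  # Clean cells: 600 expressed genes, ~6000 UMIs, zero mito counts.
  set.seed(55)
  n_genes <- 700
  genes <- c(paste0("MT-", 1:10), sprintf("GENE%03d", seq_len(n_genes - 10)))
  vals <- matrix(0, n_genes, 100)
  for (j in 1:100) {
    on <- sample(11:n_genes, 600)
    vals[on, j] <- 10
  }
  # cells 1-3: too few expressed genes
  for (j in 1:3) {
    vals[, j] <- 0
    vals[sample(11:n_genes, 499), j] <- 10
  }
  # cells 4-5: UMI total above 10,000
  for (j in 4:5) {
    vals[, j] <- 0
    vals[sample(11:n_genes, 600), j] <- 20  # 12,000 UMIs
  }
  # cells 6-7: mito fraction above 0.1
  for (j in 6:7) {
    vals[, j] <- 0
    vals[sample(11:n_genes, 590), j] <- 10
    vals[1:10, j] <- 70  # 700 of 6600 -> 0.106
  }
  expression_matrix(vals, genes, sprintf("C%03d", 1:100))
}

write_pipeline_inputs <- function(dir, seed = 1) {
  sim <- gen_planted_expression(c(12, 12), n_cells = 120, base_corr = 0.85,
                                noise_sd = 0.3, dropout_rate = 0.2, seed = seed)
  expr <- sim$expression
  labels <- rep(c("alpha", "beta"), each = 60)
  expr <- expression_matrix(expr$values, expr$gene_ids, expr$cell_ids, labels)
  dict <- gen_annotation_dict(sim$truth, coverage = 1, contamination = 0,
                              seed = seed)
  write_expression(expr, file.path(dir, "expr.tsv"))
  write_gmt(dict, file.path(dir, "sets.gmt"))
  gtn_sim <- gen_planted_network(c(12, 12), 0.6, 0.05, seed = seed)
  write_edge_list(gtn_sim$network, file.path(dir, "gtn.tsv"))
  invisible(sim)
}

pipeline_cfg <- function(dir, outdir, ...) {
  run_config(expression_path = file.path(dir, "expr.tsv"),
             gmt_path = file.path(dir, "sets.gmt"),
             outdir = outdir,
             metric = "spearman",
             thinning = list(strategy = "percentile", percentile = 15),
             qc = list(min_genes = 1, max_umi = Inf, max_mito_fraction = 1),
             min_cluster_size = 10, n_perm = 19, seed = 7, ...)
}
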