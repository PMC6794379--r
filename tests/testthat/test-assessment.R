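# Affinity score, rewiring null, permutation p-values, method ranking,
# clustering coherence, hypergeometric literature statistic.

test_that("homologous edge counting is undirected and id-based", {
  n1 <- gene_network(data.frame(from = c("A", "B", "C"), to = c("B", "C", "D")))
  n2 <- gene_network(data.frame(from = c("B", "C"), to = c("A", "E")))
  expect_equal(homologous_edges(n1, n2), 1L)  # AB == BA
  expect_equal(homologous_edges(n1, n1), n_edges(n1))
  disjoint <- gene_network(data.frame(from = "X", to = "Y"))
  expect_equal(homologous_edges(n1, disjoint), 0L)
})

test_that("affinity score matches its closed form and is symmetric", {
  gtn <- random_network(30, 0.2, seed = 1)
  net <- random_network(30, 0.15, seed = 2)
  h <- homologous_edges(net, gtn)
  expect_equal(affinity_score(net, gtn), h^2 / (n_edges(net) * n_edges(gtn)))
  expect_equal(affinity_score(net, gtn), affinity_score(gtn, net))
  expect_equal(affinity_score(gtn, gtn), 1)
  # h = 2, |E_N| = 4, |E_GTN| = 8 -> 4/32
  a <- gene_network(data.frame(from = c("A", "B", "X1", "X2"),
                               to = c("B", "C", "Y1", "Y2")))
  b <- gene_network(data.frame(from = c("A", "B", paste0("P", 1:6)),
                               to = c("B", "C", paste0("Q", 1:6))))
  expect_equal(affinity_score(a, b), 0.125)
  expect_error(affinity_score(gene_network(), gtn), "edges")
})

test_that("rewiring preserves node set, edge count and degree sequence", {
  for (s in 1:10) {
    net <- random_network(40, 0.08, seed = 100 + s)
    rw <- rewire_network(net, seed = s)
    expect_identical(sort(rw$nodes), sort(net$nodes))
    expect_equal(n_edges(rw), n_edges(net))
    dn <- scmodules:::network_degrees(net)
    dr <- scmodules:::network_degrees(rw)
    expect_identical(dr[names(dn)], dn)
  }
})

test_that("rewiring randomizes edges: different seeds, different edge sets", {
  net <- random_network(50, 0.1, seed = 7)
  r1 <- rewire_network(net, seed = 1)
  r2 <- rewire_network(net, seed = 2)
  k1 <- with(r1$edges, paste(from, to))
  k2 <- with(r2$edges, paste(from, to))
  expect_false(setequal(k1, k2))
  # triangle admits no degree-preserving alternative
  tri <- gene_network(data.frame(from = c("A", "A", "B"), to = c("B", "C", "C")))
  rt <- rewire_network(tri, seed = 3)
  expect_setequal(with(rt$edges, paste(from, to)),
                  with(tri$edges, paste(from, to)))
  single <- gene_network(data.frame(from = "A", to = "B"))
  expect_warning(rs <- rewire_network(single, seed = 1), "no degree-preserving swap")
  expect_equal(rs$edges, single$edges)
})

test_that("permutation p-value is bounded, minimal on self-comparison", {
  gtn <- random_network(60, 0.07, seed = 11)
  res <- as_pvalue(gtn, gtn, n_perm = 49, seed = 1)
  expect_equal(res$p_value, 1 / 50)  # heterogeneous degrees: no rewiring ties AS = 1
  expect_equal(res$affinity, 1)
  expect_equal(res$n_permutations, 49)
  # p never exceeds 1 and never hits 0 by construction of the estimator
  null_net <- rewire_network(gtn, seed = 5)
  res2 <- as_pvalue(null_net, gtn, n_perm = 19, seed = 2)
  expect_gte(res2$p_value, 1 / 20)
  expect_lte(res2$p_value, 1)
  expect_error(as_pvalue(gtn, gtn, n_perm = 5), ">= 19")
})

test_that("method ranking: order preservation, ties, degenerate rows", {
  results <- data.frame(
    cell_type = c("t1", "t1", "t1", "t2", "t2", "t2", "t3"),
    method = c("m1", "m2", "m3", "m1", "m2", "m3", "m1"),
    p_value = c(0.01, 0.1, 1, 1, 0.2, 0.04, 0.5))
  rk <- rank_methods(results)
  r1 <- rk$rescaled["t1", ]
  expect_equal(unname(r1[c("m1", "m3")]), c(1, 0))
  expect_true(r1[["m2"]] > 0 && r1[["m2"]] < 1)
  expect_equal(rk$best_per_row$t1, "m1")
  expect_equal(rk$best_per_row$t2, "m3")
  # single-method row rescales to 1 by convention
  expect_equal(rk$rescaled["t3", "m1"], 1)
  expect_equal(rk$best_per_row$t3, "m1")
  # tied best methods are all flagged
  tied <- data.frame(cell_type = "t", method = c("a", "b", "c"),
                     p_value = c(0.05, 0.05, 0.9))
  expect_setequal(rank_methods(tied)$best_per_row$t, c("a", "b"))
  expect_error(rank_methods(data.frame(cell_type = "t", method = "a",
                                       p_value = 0)), "> 0")
})

test_that("clustering coherence counts shared same-label genes", {
  dict <- annotation_dictionary(list(T1 = paste0("g", 1:10),
                                     T2 = paste0("g", 6:10)))
  mk_part <- function(genes, terms_by_module, mem) {
    structure(list(assignment = setNames(mem, genes),
                   module_terms = terms_by_module,
                   module_labels = terms_by_module,
                   H = length(terms_by_module)),
              class = "gene_partition")
  }
  a <- mk_part(paste0("g", 1:10), "T1", rep(1L, 10))
  expect_equal(clustering_coherence(a, a), 1)
  b <- mk_part(paste0("g", 1:10), c("T1", "T2"), rep(c(1L, 2L), each = 5))
  expect_equal(clustering_coherence(a, b), 0.5)
  disjoint <- mk_part(paste0("h", 1:10), "T1", rep(1L, 10))
  expect_equal(clustering_coherence(a, disjoint), 0)
  # unlabeled modules never count as agreeing
  u1 <- mk_part(paste0("g", 1:4), NA_character_, rep(1L, 4))
  expect_equal(clustering_coherence(u1, u1), 0)
})

test_that("hypergeometric literature statistic matches exact enumeration", {
  # population 50, successes 10, draws 10, overlap 5: sum the upper tail
  exact <- sum(vapply(5:10, function(k) {
    choose(10, k) * choose(40, 10 - k) / choose(50, 10)
  }, numeric(1)))
  expect_equal(hypergeom_literature(5, 10, 10, 50), exact, tolerance = 1e-12)
  expect_equal(hypergeom_literature(0, 10, 10, 50), 1)
  expect_equal(hypergeom_literature(10, 10, 10, 10), 1)
  expect_error(hypergeom_literature(11, 10, 10, 50), "inconsistent")
})
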