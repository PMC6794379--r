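# Modularity, annotation agreement, term selection, initialization, and
# the iterative module-detection loop.

test_that("modularity closed forms: one module is 0, singletons negative", {
  net <- two_clique_network(bridge = TRUE)
  all_one <- setNames(rep(1L, 8), net$nodes)
  expect_equal(modularity_q(all_one, net), 0)
  singles <- setNames(seq_len(8), net$nodes)
  deg <- scmodules:::network_degrees(net)
  m <- n_edges(net)
  expect_equal(modularity_q(singles, net), -sum((deg / (2 * m))^2))
  expect_lt(modularity_q(singles, net), 0)
  bad <- setNames(1L, "A1")
  expect_error(modularity_q(bad, net), "does not cover.*A2")
})

test_that("modularity agrees with igraph on random graphs and partitions", {
  for (s in 1:5) {
    net <- random_network(25, 0.15, seed = 200 + s)
    set.seed(s)
    mem <- setNames(sample(1:4, length(net$nodes), replace = TRUE), net$nodes)
    g <- as_igraph(net)
    expect_equal(modularity_q(mem, net),
                 igraph::modularity(g, mem[igraph::V(g)$name]),
                 tolerance = 1e-12)
  }
})

test_that("QGO: perfect partition scores 1, disjoint terms score 0", {
  net <- two_clique_network(bridge = FALSE)
  dict <- annotation_dictionary(list(TA = paste0("A", 1:4), TB = paste0("B", 1:4)))
  mem <- setNames(rep(1:2, each = 4), net$nodes)
  expect_equal(quality_go(mem, dict, net), 1)
  off <- annotation_dictionary(list(TX = paste0("X", 1:4)))
  expect_error(quality_go(mem, off, net), "no network node")
  # a dictionary covering only half the nodes still normalizes by N_AnnSo
  half <- annotation_dictionary(list(TA = paste0("A", 1:4)))
  expect_equal(quality_go(mem, half, net), 1)
})

test_that("QGO matches longhand set arithmetic on random partitions", {
  set.seed(31)
  net <- random_network(20, 0.2, seed = 31)
  dict <- annotation_dictionary(list(T1 = paste0("G", 1:8),
                                     T2 = paste0("G", 6:13),
                                     T3 = paste0("G", 12:20)))
  for (r in 1:50) {
    mem <- setNames(sample(1:4, 20, replace = TRUE), net$nodes)
    expect_equal(quality_go(mem, dict, net), oracle_qgo(mem, net, dict),
                 tolerance = 1e-12)
  }
})

test_that("term selection maximizes overlap with specificity tie-break", {
  dict <- annotation_dictionary(list(
    BIG = paste0("g", 1:50), SMALL = paste0("g", c(1:3, 60, 61)),
    EXACT = paste0("x", 1:4)))
  expect_equal(select_module_term(paste0("x", 1:4), dict), "EXACT")
  # overlap 3 for both BIG (size 50) and SMALL (size 5): the smaller wins
  expect_equal(select_module_term(paste0("g", 1:3), dict), "SMALL")
  expect_true(is.na(select_module_term(c("zz1", "zz2"), dict)))
  # lexicographic on full ties
  tied <- annotation_dictionary(list(B = c("a", "b"), A = c("a", "c")))
  expect_equal(select_module_term("a", tied), "A")
})

test_that("initialization: term seeding, fallbacks, determinism", {
  net <- two_clique_network(bridge = FALSE)
  dict <- annotation_dictionary(list(TA = paste0("A", 1:4), TB = paste0("B", 1:4)))
  p <- initialize_partition(net, dict, seed = 1)
  expect_equal(p$H, 2L)
  expect_setequal(p$module_terms, c("TA", "TB"))
  # empty dictionary: all singletons
  p0 <- initialize_partition(net, NULL, seed = 1)
  expect_equal(p0$H, 8L)
  # same seed twice gives identical partitions
  half <- annotation_dictionary(list(TA = paste0("A", 1:4)))
  p1 <- initialize_partition(net, half, seed = 7)
  p2 <- initialize_partition(net, half, seed = 7)
  expect_identical(p1, p2)
})

test_that("pure-topology detection finds the brute-force optimum on two cliques", {
  net <- two_clique_network(bridge = FALSE)
  part <- detect_modules(net, dict = NULL, seed = 4, topology_weight = 1)
  expect_equal(part$H, 2L)
  split_by_clique <- length(unique(part$assignment[paste0("A", 1:4)])) == 1 &&
    length(unique(part$assignment[paste0("B", 1:4)])) == 1
  expect_true(split_by_clique)
  # exhaustive maximum over all 4,140 partitions of the 8 nodes
  best <- max(vapply(set_partitions(8), function(mem) {
    oracle_modularity(mem, net)
  }, numeric(1)))
  expect_equal(modularity_q(part, net), best, tolerance = 1e-12)
})

test_that("local optimum beats 95% of enumerated partitions on a small fixture", {
  net <- two_clique_network(bridge = TRUE)
  dict <- annotation_dictionary(list(TA = paste0("A", 1:4),
                                     TB = paste0("B", 1:4),
                                     TMIX = c("A1", "B1", "B2")))
  part <- detect_modules(net, dict, seed = 2, topology_weight = 0.5)
  obj <- 0.5 * modularity_q(part, net) + 0.5 * quality_go(part, dict, net)
  objs <- vapply(set_partitions(8), function(mem) {
    memv <- setNames(mem, net$nodes)
    0.5 * oracle_modularity(mem, net) + 0.5 * oracle_qgo(memv, net, dict)
  }, numeric(1))
  expect_gte(mean(objs <= obj + 1e-12), 0.95)
})

test_that("trajectory audit: recorded Q/QGO equal from-scratch recomputation", {
  sim <- gen_planted_network(c(15, 15, 15), 0.5, 0.05, seed = 9)
  dict <- gen_annotation_dict(sim$truth, coverage = 0.8, contamination = 0.1,
                              seed = 9)
  part <- detect_modules(sim$network, dict, seed = 9)
  last <- part$trajectory[nrow(part$trajectory), ]
  expect_equal(modularity_q(part, sim$network), last$Q, tolerance = 1e-10)
  expect_equal(quality_go(part, dict, sim$network), last$QGO, tolerance = 1e-10)
  # score bounds hold at every iteration
  expect_true(all(part$trajectory$Q >= -1 & part$trajectory$Q <= 1))
  expect_true(all(part$trajectory$QGO >= 0 & part$trajectory$QGO <= 1))
  # convergence contract
  if (isTRUE(part$converged)) {
    k <- nrow(part$trajectory)
    expect_lt(abs(part$trajectory$Q[k] - part$trajectory$Q[k - 1]), 1e-4)
    expect_lt(abs(part$trajectory$QGO[k] - part$trajectory$QGO[k - 1]), 1e-4)
  }
})

test_that("detection is seed-deterministic and covers every node once", {
  sim <- gen_planted_network(c(12, 12), 0.5, 0.05, seed = 3)
  dict <- gen_annotation_dict(sim$truth, coverage = 0.7, seed = 3)
  p1 <- detect_modules(sim$network, dict, seed = 42)
  p2 <- detect_modules(sim$network, dict, seed = 42)
  expect_identical(p1, p2)
  expect_setequal(names(p1$assignment), sim$network$nodes)
  expect_equal(p1$H, length(unique(p1$assignment)))
  expect_true(all(tabulate(p1$assignment, p1$H) > 0))  # no empty module
})

test_that("planted four-block recovery with exact block terms", {
  skip_if_not_installed("mclust")
  sim <- gen_planted_network(c(30, 30, 30, 30), 0.4, 0.02, seed = 5)
  dict <- gen_annotation_dict(sim$truth, coverage = 1, contamination = 0,
                              seed = 5)
  aris <- vapply(1:3, function(s) {
    part <- detect_modules(sim$network, dict, seed = s)
    mclust::adjustedRandIndex(
      part$assignment[names(sim$truth$block_assignment)],
      sim$truth$block_assignment)
  }, numeric(1))
  expect_gte(median(aris), 0.9)
})

test_that("shuffled annotations never beat the planted dictionary on QGO", {
  sim <- gen_planted_network(c(20, 20, 20), 0.4, 0.03, seed = 13)
  dict <- gen_annotation_dict(sim$truth, coverage = 1, contamination = 0,
                              seed = 13)
  qgo_true <- vapply(1:5, function(s) {
    p <- detect_modules(sim$network, dict, seed = s)
    p$trajectory$QGO[nrow(p$trajectory)]
  }, numeric(1))
  set.seed(99)
  genes <- sample(names(sim$truth$block_assignment))
  sizes <- lengths(dict$sets)
  shuffled <- annotation_dictionary(setNames(
    split(genes[seq_len(sum(sizes))], rep(seq_along(sizes), sizes)),
    names(dict$sets)))
  qgo_shuf <- vapply(1:5, function(s) {
    p <- detect_modules(sim$network, shuffled, seed = s)
    p$trajectory$QGO[nrow(p$trajectory)]
  }, numeric(1))
  expect_lte(median(qgo_shuf), median(qgo_true))
})
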