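# Thinning strategies: exact counts, nesting/monotonicity, percentile
# ties, power-law fitting, and grid-search selection.

test_that("absolute threshold keeps exactly the pairs at or above t", {
  w <- c(0.9, 0.5, 0.2, 0.1, 0.05, 0.01)
  mat <- matrix(0, 4, 4, dimnames = list(paste0("G", 1:4), paste0("G", 1:4)))
  mat[upper.tri(mat)] <- w
  mat <- mat + t(mat)
  C <- fake_coexpression(mat)
  expect_equal(n_edges(thin_abs_threshold(C, 0.4)), 2L)
  expect_equal(n_edges(thin_abs_threshold(C, 0)), 6L)     # all defined pairs
  expect_equal(n_edges(thin_abs_threshold(C, 0.95)), 0L)  # above max |c|
  # boundary is inclusive
  expect_equal(n_edges(thin_abs_threshold(C, 0.5)), 2L)
})

test_that("threshold edge sets are nested and counts non-increasing in t", {
  set.seed(5)
  n <- 12
  mat <- matrix(0, n, n)
  mat[upper.tri(mat)] <- runif(choose(n, 2), -1, 1)
  mat <- mat + t(mat)
  dimnames(mat) <- list(paste0("G", 1:n), paste0("G", 1:n))
  C <- fake_coexpression(mat)
  ts <- seq(0, 1, by = 0.1)
  nets <- lapply(ts, function(t) thin_abs_threshold(C, t))
  counts <- vapply(nets, n_edges, integer(1))
  expect_true(all(diff(counts) <= 0))
  for (i in seq_len(length(ts) - 1)) {
    lo <- with(nets[[i]]$edges, paste(from, to))
    hi <- with(nets[[i + 1]]$edges, paste(from, to))
    expect_true(all(hi %in% lo))
  }
  # negative weights survive with sign
  expect_true(any(nets[[1]]$edges$weight < 0))
})

test_that("percentile thinning: exact count without ties, all ties kept", {
  n <- 10  # 45 pairs
  set.seed(9)
  w <- sample(seq(0.01, 0.99, length.out = choose(n, 2)))
  mat <- matrix(0, n, n, dimnames = list(paste0("G", 1:n), paste0("G", 1:n)))
  mat[upper.tri(mat)] <- w
  mat <- mat + t(mat)
  C <- fake_coexpression(mat)
  expect_equal(n_edges(thin_percentile(C, 20)), 9L)  # 45 * 0.2, all distinct
  # q = 100 retains the same pairs as threshold 0
  all_pairs <- thin_percentile(C, 100)
  expect_equal(n_edges(all_pairs), n_edges(thin_abs_threshold(C, 0)))

  # 5-way tie spanning the 9th rank: all tied values retained
  w2 <- c(sort(w, decreasing = TRUE)[1:7], rep(0.5, 5),
          seq(0.4, 0.01, length.out = 45 - 12))
  mat2 <- matrix(0, n, n, dimnames = dimnames(mat))
  mat2[upper.tri(mat2)] <- w2
  mat2 <- mat2 + t(mat2)
  net2 <- thin_percentile(fake_coexpression(mat2), 20)
  expect_equal(n_edges(net2), 12L)
  expect_gte(n_edges(net2), ceiling(0.2 * 45))
})

test_that("undefined (NA) entries never become edges; isolated genes drop", {
  mat <- matrix(c(0, 0.9, NA, 0.9, 0, NA, NA, NA, 0), 3, 3,
                dimnames = list(c("A", "B", "Z"), c("A", "B", "Z")))
  net <- thin_abs_threshold(fake_coexpression(mat), 0.1)
  expect_equal(n_edges(net), 1L)
  expect_setequal(net$nodes, c("A", "B"))  # Z had only undefined entries
})

test_that("power-law MLE recovers the exponent of an inverse-CDF sample", {
  d <- sample_power_law_degrees(5000, 2.5, seed = 101)
  fit <- fit_degree_power_law(d)
  expect_true(fit$defined)
  expect_gte(fit$gamma_hat, 2.4)
  expect_lte(fit$gamma_hat, 2.6)
  # MLE invariant under duplicating the multiset
  fit2 <- fit_degree_power_law(c(d, d))
  expect_equal(fit2$gamma_hat, fit$gamma_hat, tolerance = 1e-8)
  # degenerate distribution flagged undefined
  expect_false(fit_degree_power_law(rep(4L, 100))$defined)
})

test_that("scale-free grid search picks the planted cutoff", {
  planted <- gen_power_law_network(400, gamma = 2.5, seed = 21)
  nodes <- planted$nodes
  # planted scale-free edges at weight 0.8; near-regular noise below 0.5
  noise <- random_network(length(nodes), 0.05, seed = 22)
  mat <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(noise$edges))) {
    a <- match(noise$edges$from[i], paste0("G", seq_along(nodes)))
    b <- match(noise$edges$to[i], paste0("G", seq_along(nodes)))
    mat[a, b] <- mat[b, a] <- 0.4
  }
  for (i in seq_len(nrow(planted$edges))) {
    mat[planted$edges$from[i], planted$edges$to[i]] <- 0.8
    mat[planted$edges$to[i], planted$edges$from[i]] <- 0.8
  }
  C <- fake_coexpression(mat)
  res <- thin_scale_free(C, cutoff_grid = c(0.3, 0.6), gamma_target = 2.5)
  expect_equal(res$fit$cutoff, 0.6)
  expect_equal(sort(with(res$network$edges, paste(from, to))),
               sort(with(planted$edges, paste(from, to))))
  expect_equal(nrow(res$log), 2)

  # degenerate single-cutoff grid equals plain thresholding
  single <- thin_scale_free(C, cutoff_grid = 0.6)
  thr <- thin_abs_threshold(C, 0.6)
  expect_equal(sort(with(single$network$edges, paste(from, to))),
               sort(with(thr$edges, paste(from, to))))

  # cutoffs above max |c| are skipped; a grid of only those errors
  res2 <- thin_scale_free(C, cutoff_grid = c(0.6, 0.95))
  expect_true(is.na(res2$log$score[res2$log$cutoff == 0.95]))
  expect_error(thin_scale_free(C, cutoff_grid = 0.95), "denser")
})
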