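# Joint topology + annotation module detection.
#
# A partition of the gene network is scored by two quantities:
#   Q   — Newman modularity, sum over modules of
#         e_h/|E| - (d_h / 2|E|)^2  (within-module edge excess over a
#         degree-matched random graph), in [-1, 1];
#   QGO — agreement between the partition and its selected annotation
#         terms: sum over modules of |term-set ∩ members| / N_AnnSo,
#         where N_AnnSo is the number of network nodes carrying at least
#         one dictionary term, in [0, 1].
# The optimizer seeds modules from dictionary terms, then iterates local
# node moves maximizing the blended gain
#   dS = topology_weight * dQ + (1 - topology_weight) * dQGO,
# reassigning each module's term after every sweep, until Q and QGO both
# change by less than T = 1e-4 between consecutive iterations.

UNLABELED <- "unlabeled"

#' @noRd
partition_membership <- function(part) {
  if (inherits(part, "gene_partition")) return(part$assignment)
  if (is.null(names(part))) stopf("membership vector must be named by gene id")
  part
}

#' Newman modularity of a partition
#'
#' `Q = sum_h [ e_h/|E| - (d_h / (2|E|))^2 ]` with `e_h` the number of
#' edges internal to module `h` and `d_h` the summed degree of its nodes.
#' Edge counts are unweighted. Positive values mean more within-module
#' links than expected at random; the all-in-one partition scores exactly
#' 0.
#'
#' @param part A [detect_modules()] partition or a membership vector named
#'   by gene id, covering every network node.
#' @param net A [gene_network()] with at least one edge.
#' @return Scalar in `[-1, 1]`.
#' @export
modularity_q <- function(part, net) {
  mem <- partition_membership(part)
  missing <- setdiff(net$nodes, names(mem))
  if (length(missing) > 0) {
    stopf("partition does not cover network node '%s'", missing[1])
  }
  m <- n_edges(net)
  if (m == 0) stopf("modularity is undefined on an edgeless network")
  mem <- factor(mem[net$nodes])
  mf <- mem[match(net$edges$from, net$nodes)]
  mt <- mem[match(net$edges$to, net$nodes)]
  e_h <- table(factor(mf[mf == mt], levels = levels(mem)))
  d_h <- tapply(network_degrees(net)[net$nodes], mem, sum, default = 0)
  sum(as.numeric(e_h) / m - (as.numeric(d_h[names(e_h)]) / (2 * m))^2)
}

#' Annotation agreement (QGO) of a partition
#'
#' `QGO = sum_h |genes(term_h) ∩ members(h)| / N_AnnSo` where `term_h` is
#' module `h`'s assigned annotation term and `N_AnnSo` counts network
#' nodes with at least one dictionary term. Since modules are disjoint and
#' each gene contributes at most once (to its own module), QGO lies in
#' `[0, 1]`; 1 means every annotated node sits in a module whose term
#' contains it.
#'
#' @param part A [detect_modules()] partition (its `module_terms` are
#'   used), or a bare membership vector, in which case each module gets
#'   the term chosen by [select_module_term()].
#' @param dict An [annotation_dictionary()].
#' @param net The [gene_network()] the partition covers.
#' @return Scalar in `[0, 1]`.
#' @export
quality_go <- function(part, dict, net) {
  mem <- partition_membership(part)
  missing <- setdiff(net$nodes, names(mem))
  if (length(missing) > 0) {
    stopf("partition does not cover network node '%s'", missing[1])
  }
  mem <- mem[net$nodes]
  n_annso <- sum(vapply(net$nodes, function(g) {
    any(vapply(dict$sets, function(s) g %in% s, logical(1)))
  }, logical(1)))
  if (n_annso == 0) stopf("no network node carries any dictionary term")
  members_by_mod <- split(net$nodes, mem)
  if (inherits(part, "gene_partition")) {
    terms <- part$module_terms[as.integer(names(members_by_mod))]
  } else {
    terms <- vapply(members_by_mod, function(g) select_module_term(g, dict),
                    character(1))
  }
  total <- 0
  for (i in seq_along(members_by_mod)) {
    t <- terms[[i]]
    if (is.na(t)) next
    total <- total + length(intersect(dict$sets[[t]], members_by_mod[[i]]))
  }
  total / n_annso
}

#' Choose the annotation term that best models a gene set
#'
#' Returns the term with the largest overlap with `members`; ties prefer
#' the smaller (more specific) gene set, then the lexicographically first
#' term id. `NA` when no term intersects the members.
#'
#' @param members Nonempty character vector of gene ids.
#' @param dict An [annotation_dictionary()].
#' @return A term id, or `NA_character_` (unlabeled).
#' @export
select_module_term <- function(members, dict) {
  if (length(members) == 0) stopf("members must be nonempty")
  if (length(dict$sets) == 0) return(NA_character_)
  overlap <- vapply(dict$sets, function(s) length(intersect(s, members)),
                    integer(1))
  if (max(overlap) == 0) return(NA_character_)
  sizes <- lengths(dict$sets)
  ids <- names(dict$sets)
  ord <- order(-overlap, sizes, ids)
  ids[ord[1]]
}

#' @noRd
make_gene_partition <- function(nodes, mem, term_ids, dict, trajectory,
                                converged, params = list()) {
  # compact module ids and order by first appearance
  f <- factor(mem, levels = unique(mem))
  idx <- as.integer(f)
  H <- nlevels(f)
  terms <- term_ids[as.integer(levels(f))]
  labels <- ifelse(is.na(terms), UNLABELED,
                   ifelse(is.na(dict$labels[terms]) | !nzchar(dict$labels[terms]),
                          terms, dict$labels[terms]))
  sizes <- tabulate(idx, H)
  colors <- integer(H)
  colors[order(-sizes, seq_len(H))] <- seq_len(H)
  structure(list(assignment = stats::setNames(idx, nodes),
                 module_terms = as.character(terms),
                 module_labels = as.character(labels),
                 H = H, module_sizes = sizes, module_colors = colors,
                 trajectory = trajectory, converged = converged,
                 params = params),
            class = "gene_partition")
}

#' @noRd
module_label <- function(part, idx) {
  lab <- part$module_labels[idx]
  ifelse(is.na(lab), UNLABELED, lab)
}

#' @export
print.gene_partition <- function(x, ...) {
  cat(sprintf("<gene_partition> %d genes in %d modules", length(x$assignment), x$H))
  if (nrow(x$trajectory) > 0) {
    last <- x$trajectory[nrow(x$trajectory), ]
    cat(sprintf("; Q=%.4f QGO=%.4f after %d iteration(s)%s",
                last$Q, last$QGO, nrow(x$trajectory),
                if (isTRUE(x$converged)) "" else " [not converged]"))
  }
  cat("\n")
  invisible(x)
}

#' Seed an initial partition from dictionary terms
#'
#' Every dictionary term present in the network spawns a candidate module.
#' A gene annotated by several terms goes to the term with the largest
#' network overlap (ties: smaller full gene set, then lexicographic id) —
#' the same preference order as [select_module_term()]. Unannotated genes
#' join the module of their highest-|weight| already-assigned neighbor, or
#' form singletons. Deterministic given the seed (the seed shuffles the
#' order in which unannotated genes are placed).
#'
#' @param net A nonempty [gene_network()].
#' @param dict An [annotation_dictionary()]; may be empty
#'   (`annotation_dictionary(list())` is rejected by its constructor, so
#'   pass `NULL` for the no-annotation case), giving an all-singleton
#'   start.
#' @param seed Integer seed.
#' @return A `gene_partition` (with an empty trajectory).
#' @export
initialize_partition <- function(net, dict = NULL, seed = 1) {
  nodes <- net$nodes
  n <- length(nodes)
  if (n == 0) stopf("network is empty")
  sets <- if (is.null(dict)) list() else dict$sets
  mem <- rep(NA_integer_, n)
  names(mem) <- nodes
  term_of_module <- character(0)
  if (length(sets) > 0) {
    net_overlap <- vapply(sets, function(s) length(intersect(s, nodes)), integer(1))
    sizes <- lengths(sets)
    ids <- names(sets)
    # preference rank of each term (1 = most preferred)
    pref <- order(-net_overlap, sizes, ids)
    rank_of_term <- stats::setNames(match(seq_along(ids), pref), ids)
    gene_term <- rep(NA_character_, n)
    for (ti in ids[net_overlap > 0]) {
      hit <- nodes %in% sets[[ti]]
      better <- hit & (is.na(gene_term) | rank_of_term[ti] < rank_of_term[gene_term])
      gene_term[which(better)] <- ti
    }
    used_terms <- unique(gene_term[!is.na(gene_term)])
    for (ti in used_terms) {
      term_of_module <- c(term_of_module, ti)
      mem[gene_term == ti] <- length(term_of_module)
    }
  }
  # unannotated genes: join the term-seeded module of their strongest
  # neighbor, else form singletons (an empty dictionary thus yields the
  # all-singleton start)
  n_term_modules <- length(term_of_module)
  adj <- adjacency_list(net)
  todo <- with_seed(seed, sample(which(is.na(mem))))
  for (v in todo) {
    nbrs <- adj$nbr[[v]]
    in_term_mod <- !is.na(mem[nbrs]) & mem[nbrs] <= n_term_modules
    assigned <- nbrs[in_term_mod]
    if (length(assigned) > 0) {
      wts <- adj$wt[[v]][in_term_mod]
      best <- assigned[order(-abs(wts), nodes[assigned])][1]
      mem[v] <- mem[best]
    } else {
      term_of_module <- c(term_of_module, NA_character_)
      mem[v] <- length(term_of_module)
    }
  }
  dict_safe <- dict %||% list(labels = character(0))
  make_gene_partition(nodes, unname(mem), term_of_module, dict_safe,
                      trajectory = data.frame(iteration = integer(),
                                              Q = numeric(), QGO = numeric()),
                      converged = NA, params = list(seed = seed))
}

#' @noRd
adjacency_list <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  ei <- match(net$edges$from, nodes)
  ek <- match(net$edges$to, nodes)
  w <- net$edges$weight
  nbr <- vector("list", n)
  wt <- vector("list", n)
  ends <- c(ei, ek)
  other <- c(ek, ei)
  ww <- c(w, w)
  o <- order(ends)
  runs <- split(seq_along(ends)[o], ends[o])
  for (v in seq_len(n)) nbr[[v]] <- integer(0)
  for (v in seq_len(n)) wt[[v]] <- numeric(0)
  for (key in names(runs)) {
    v <- as.integer(key)
    nbr[[v]] <- other[runs[[key]]]
    wt[[v]] <- ww[runs[[key]]]
  }
  list(nbr = nbr, wt = wt, deg = lengths(nbr))
}

#' Detect annotated functional modules in a gene network
#'
#' Iterative local optimization of the blended objective
#' `topology_weight * Q + (1 - topology_weight) * QGO` (see
#' [modularity_q()], [quality_go()]). Each iteration (1) fixes every
#' module's annotation term via [select_module_term()], (2) sweeps the
#' nodes in seed-shuffled order, moving each to the adjacent module — or
#' to a fresh singleton — with the largest positive blended gain (genes
#' are attracted to modules whose term contains them), (3) dissolves
#' emptied modules, and (4) records `(Q, QGO)`. The run stops when two
#' consecutive iterations change both Q and QGO by less than `T`
#' (default 1e-4), or at `max_iter` (the result then carries
#' `converged = FALSE`).
#'
#' With `density_mode = TRUE` the returned partition is the iterate with
#' the highest mean within-module edge density (singletons count 0)
#' instead of the final iterate — this weights the network structure over
#' the annotation source when the dictionary is suspect.
#'
#' @param net A nonempty [gene_network()] with at least one edge.
#' @param dict An [annotation_dictionary()], or `NULL` for pure-topology
#'   optimization.
#' @param T Convergence threshold on consecutive Q and QGO changes.
#' @param max_iter Iteration cap.
#' @param seed Integer seed (node sweep order and initialization).
#' @param topology_weight Blend weight in `[0, 1]`: 1 = modularity only,
#'   0 = annotation agreement only. Default 0.5.
#' @param density_mode Select the max-mean-density iterate (see above).
#' @param init Optional starting `gene_partition`; defaults to
#'   [initialize_partition()].
#' @return A `gene_partition`: named `assignment` (gene -> module index),
#'   `module_terms` / `module_labels` (term per module, `NA`/"unlabeled"
#'   sentinel when nothing overlaps), `H`, per-iteration `trajectory`
#'   (`iteration`, `Q`, `QGO`), and `converged`.
#' @examples
#' sim <- gen_planted_network(c(8, 8), p_in = 1, p_out = 0, seed = 1)
#' part <- detect_modules(sim$network, dict = NULL, seed = 1)
#' part$H
#' @export
detect_modules <- function(net, dict = NULL, T = 1e-4, max_iter = 200,
                           seed = 1, topology_weight = 0.5,
                           density_mode = FALSE, init = NULL) {
  if (T <= 0) stopf("T must be positive")
  if (max_iter < 1) stopf("max_iter must be >= 1")
  if (topology_weight < 0 || topology_weight > 1) {
    stopf("topology_weight must be in [0, 1]")
  }
  nodes <- net$nodes
  n <- length(nodes)
  m <- n_edges(net)
  if (n == 0 || m == 0) stopf("network must have nodes and at least one edge")

  adj <- adjacency_list(net)
  deg <- adj$deg

  # dictionary bookkeeping on node indices
  sets <- if (is.null(dict)) list() else dict$sets
  term_ids <- names(sets)
  term_sizes <- lengths(sets)
  term_members <- lapply(sets, function(s) which(nodes %in% s))
  node_terms <- vector("list", n)
  for (ti in seq_along(term_members)) {
    for (v in term_members[[ti]]) node_terms[[v]] <- c(node_terms[[v]], ti)
  }
  annotated <- lengths(node_terms) > 0
  n_annso <- sum(annotated)
  # term a fresh singleton {v} would adopt: smallest then lexicographic
  node_best_term <- rep(NA_integer_, n)
  for (v in which(annotated)) {
    ts <- node_terms[[v]]
    node_best_term[v] <- ts[order(term_sizes[ts], term_ids[ts])][1]
  }
  select_term_idx <- function(member_idx) {
    if (length(term_members) == 0) return(NA_integer_)
    overlap <- vapply(term_members, function(tm) sum(tm %in% member_idx),
                      integer(1))
    if (max(overlap) == 0) return(NA_integer_)
    order(-overlap, term_sizes, term_ids)[1]
  }
  go_weight <- if (n_annso > 0) (1 - topology_weight) / n_annso else 0

  part0 <- init %||% initialize_partition(net, dict, seed = seed)
  missing <- setdiff(nodes, names(part0$assignment))
  if (length(missing) > 0) stopf("init partition does not cover node '%s'", missing[1])
  mem <- unname(part0$assignment[nodes])

  recount <- function(mem, n_mod) {
    mf <- mem[match(net$edges$from, nodes)]
    mt <- mem[match(net$edges$to, nodes)]
    e_in <- tabulate(ifelse(mf == mt, mf, NA_integer_), n_mod)
    d_sum <- vapply(seq_len(n_mod), function(h) sum(deg[mem == h]), numeric(1))
    list(e_in = e_in, d_sum = d_sum)
  }
  compact <- function(mem) as.integer(factor(mem, levels = unique(mem)))

  mem <- compact(mem)
  trajectory <- data.frame(iteration = integer(), Q = numeric(), QGO = numeric())
  best_density <- -Inf
  best_state <- NULL
  converged <- FALSE
  term_of <- integer(0)

  rng_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, max_iter))

  for (iter in seq_len(max_iter)) {
    n_mod <- max(mem)
    st <- recount(mem, n_mod)
    e_in <- st$e_in
    d_sum <- st$d_sum
    # (1) assign each module its term
    term_of <- vapply(seq_len(n_mod), function(h) select_term_idx(which(mem == h)),
                      integer(1))
    # (2) seed-shuffled local move sweep
    sweep_order <- with_seed(rng_seeds[iter], sample.int(n))
    for (v in sweep_order) {
      cur <- mem[v]
      kv <- deg[v]
      nbrs <- adj$nbr[[v]]
      nbr_mods <- mem[nbrs]
      k_to <- table(nbr_mods)
      k_cur <- if (as.character(cur) %in% names(k_to)) k_to[[as.character(cur)]] else 0L
      cand <- unique(nbr_mods)
      cand <- cand[cand != cur]
      v_terms <- node_terms[[v]]
      in_cur <- !is.na(term_of[cur]) && term_of[cur] %in% v_terms
      d_cur_rm <- d_sum[cur] - kv
      gain_best <- 0
      move_to <- cur
      for (b in cand) {
        k_b <- k_to[[as.character(b)]]
        dq <- (k_b - k_cur) / m -
          ((d_sum[b] + kv)^2 + d_cur_rm^2 - d_sum[b]^2 - d_sum[cur]^2) / (4 * m^2)
        in_b <- !is.na(term_of[b]) && term_of[b] %in% v_terms
        g <- topology_weight * dq + go_weight * (in_b - in_cur)
        if (g > gain_best + 1e-12) {
          gain_best <- g
          move_to <- b
        }
      }
      # fresh singleton candidate (only worthwhile if v is not already alone)
      if (sum(mem == cur) > 1) {
        dq <- (0 - k_cur) / m - (kv^2 + d_cur_rm^2 - d_sum[cur]^2) / (4 * m^2)
        in_new <- !is.na(node_best_term[v])
        g <- topology_weight * dq + go_weight * (in_new - in_cur)
        if (g > gain_best + 1e-12) {
          gain_best <- g
          move_to <- 0L  # sentinel: new module
        }
      }
      if (move_to != cur) {
        if (move_to == 0L) {
          n_mod <- n_mod + 1L
          e_in <- c(e_in, 0L)
          d_sum <- c(d_sum, 0)
          term_of <- c(term_of, if (is.na(node_best_term[v])) NA_integer_ else node_best_term[v])
          move_to <- n_mod
          k_b <- 0L
        } else {
          k_b <- k_to[[as.character(move_to)]]
        }
        e_in[cur] <- e_in[cur] - k_cur
        d_sum[cur] <- d_sum[cur] - kv
        e_in[move_to] <- e_in[move_to] + k_b
        d_sum[move_to] <- d_sum[move_to] + kv
        mem[v] <- move_to
      }
    }
    # (3) dissolve empty modules, (4) score and record
    mem <- compact(mem)
    n_mod <- max(mem)
    st <- recount(mem, n_mod)
    term_of <- vapply(seq_len(n_mod), function(h) select_term_idx(which(mem == h)),
                      integer(1))
    Q <- sum(st$e_in / m - (st$d_sum / (2 * m))^2)
    QGO <- if (n_annso > 0) {
      sum(vapply(seq_len(n_mod), function(h) {
        if (is.na(term_of[h])) return(0L)
        sum(term_members[[term_of[h]]] %in% which(mem == h))
      }, integer(1))) / n_annso
    } else 0
    trajectory <- rbind(trajectory,
                        data.frame(iteration = iter, Q = Q, QGO = QGO))
    if (density_mode) {
      sizes <- tabulate(mem, n_mod)
      dens <- ifelse(sizes >= 2, st$e_in / choose(sizes, 2), 0)
      md <- mean(dens)
      if (md > best_density) {
        best_density <- md
        best_state <- list(mem = mem, term_of = term_of)
      }
    }
    if (iter >= 2) {
      prev <- trajectory[iter - 1, ]
      if (abs(Q - prev$Q) < T && abs(QGO - prev$QGO) < T) {
        converged <- TRUE
        break
      }
    }
  }

  if (density_mode && !is.null(best_state)) {
    mem <- best_state$mem
    term_of <- best_state$term_of
  }
  term_chr <- ifelse(is.na(term_of), NA_character_, term_ids[term_of])
  dict_safe <- dict %||% list(labels = character(0))
  params <- list(T = T, max_iter = max_iter, seed = seed,
                 topology_weight = topology_weight, density_mode = density_mode)
  make_gene_partition(nodes, mem, term_chr, dict_safe, trajectory, converged,
                      params)
}
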