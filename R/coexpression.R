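# Gene-gene coexpression within one cell cluster.
#
# Correlation metrics (Pearson, Spearman, Kendall tau-b) come from
# stats::cor. The proportionality coefficients rho and phi operate on
# log-transformed values after a pseudocount, following the compositional
# data literature: for log vectors lx, ly,
#   phi(x, y) = var(lx - ly) / var(lx)            (asymmetric)
#   rho(x, y) = 1 - var(lx - ly) / (var(lx) + var(ly))
#             = 2 cov(lx, ly) / (var(lx) + var(ly))
# Both are invariant to multiplying either vector by a positive constant,
# which makes them robust to per-gene scale and attractive for sparse,
# dropout-ridden single-cell counts.

COEXPR_METRICS <- c("pearson", "spearman", "kendall", "rho", "phi")

#' Compute the symmetric gene-gene coexpression matrix of one cluster
#'
#' Each entry `c[i, k]` measures expression similarity of genes `i` and `k`
#' across the cells of a single cluster. Genes with zero variance across
#' the cells (or zero log-variance for `rho`/`phi`) yield `NA` entries;
#' downstream thinning treats `NA` as "no edge".
#'
#' phi is a dissimilarity (0 = perfectly proportional) and asymmetric as a
#' pairwise function; the matrix entry symmetrizes by averaging
#' `phi(x, y)` and `phi(y, x)`.
#'
#' @param expr An [expression_matrix()]. When `cluster` is given the matrix
#'   is first restricted to that cluster's cells.
#' @param metric One of `"pearson"`, `"spearman"`, `"kendall"`, `"rho"`,
#'   `"phi"`.
#' @param cluster Optional cluster label to subset to.
#' @param pseudocount Nonnegative value added before the log transform for
#'   `rho`/`phi` (default 1). Must be positive when zeros are present.
#' @return A symmetric numeric matrix of class `coexpression_matrix` with
#'   gene ids as dimnames and attributes `metric` and `n_cells`. The
#'   diagonal is set to `NA` (ignored downstream).
#' @examples
#' expr <- expression_matrix(matrix(rpois(40, 5), nrow = 4),
#'                           paste0("G", 1:4), paste0("c", 1:10))
#' coexpression(expr, "spearman")
#' @export
coexpression <- function(expr, metric = COEXPR_METRICS, cluster = NULL,
                         pseudocount = 1) {
  metric <- match.arg(metric)
  if (!is.null(cluster)) expr <- subset_cluster(expr, cluster)
  x <- expr$values
  if (ncol(x) < 3) stopf("need >= 3 cells to compute coexpression, got %d", ncol(x))
  if (nrow(x) < 2) stopf("need >= 2 genes, got %d", nrow(x))
  if (metric %in% c("pearson", "spearman", "kendall")) {
    zero_var <- apply(x, 1, stats::var) == 0
    C <- suppressWarnings(stats::cor(t(x), method = metric))
    C[zero_var, ] <- NA_real_
    C[, zero_var] <- NA_real_
  } else {
    if (pseudocount < 0) stopf("pseudocount must be nonnegative")
    if (pseudocount == 0 && any(x <= 0)) {
      stopf("%s requires strictly positive values; use a positive pseudocount",
            metric)
    }
    L <- log(x + pseudocount)
    V <- stats::cov(t(L))
    v <- diag(V)
    if (metric == "rho") {
      denom <- outer(v, v, "+")
      C <- 2 * V / denom
      C[denom == 0] <- NA_real_
    } else {
      # var(lx - ly) = v_x + v_y - 2 cov; average of the two asymmetric phis
      dvar <- outer(v, v, "+") - 2 * V
      inv <- ifelse(v > 0, 1 / v, NA_real_)
      C <- dvar * (outer(inv, rep(1, length(v))) + outer(rep(1, length(v)), inv)) / 2
      C[pmax(abs(dvar), 0) < .Machine$double.eps * 4] <- 0  # numeric cleanup
      C[is.na(outer(inv, inv))] <- NA_real_
    }
    zero_var <- v == 0
    C[zero_var, ] <- NA_real_
    C[, zero_var] <- NA_real_
  }
  C <- (C + t(C)) / 2  # enforce exact symmetry against FP asymmetry
  diag(C) <- NA_real_
  dimnames(C) <- list(expr$gene_ids, expr$gene_ids)
  structure(C, metric = metric, n_cells = ncol(x), class = c("coexpression_matrix", "matrix"))
}

#' Proportionality dissimilarity phi of two positive vectors
#'
#' `phi(x, y) = var(log x - log y) / var(log x)`: zero iff `y = c * x` for
#' a positive constant `c`. Note the asymmetry in the denominator.
#'
#' @param x,y Strictly positive numeric vectors of equal length `>= 3`.
#' @return Nonnegative scalar, or `NA` when `var(log x)` is zero.
#' @export
phi_prop <- function(x, y) {
  check_prop_input(x, y)
  lx <- log(x); ly <- log(y)
  vx <- stats::var(lx)
  if (vx == 0) return(NA_real_)
  stats::var(lx - ly) / vx
}

#' Proportionality coefficient rho of two positive vectors
#'
#' `rho(x, y) = 1 - var(log x - log y) / (var(log x) + var(log y))`, in
#' `[-1, 1]`; equals 1 iff `log y = log x + const`.
#'
#' @param x,y Strictly positive numeric vectors of equal length `>= 3`.
#' @return Scalar in `[-1, 1]`, or `NA` when both log-variances are zero.
#' @export
rho_prop <- function(x, y) {
  check_prop_input(x, y)
  lx <- log(x); ly <- log(y)
  denom <- stats::var(lx) + stats::var(ly)
  if (denom == 0) return(NA_real_)
  1 - stats::var(lx - ly) / denom
}

#' @noRd
check_prop_input <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3) stopf("need >= 3 observations")
  if (any(x <= 0) || any(y <= 0)) stopf("x and y must be strictly positive")
  invisible(TRUE)
}

#' @export
print.coexpression_matrix <- function(x, ...) {
  cat(sprintf("<coexpression_matrix> %d genes, metric=%s, %d cells\n",
              nrow(x), attr(x, "metric"), attr(x, "n_cells")))
  invisible(x)
}
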