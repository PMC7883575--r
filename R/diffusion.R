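# Random walk with restarts over the combined graph.
#
# The walk matrix is the row normalization W = D^-1 A. With restart
# probability alpha in (0,1) the walk converges, and its stationary
# information flow has the closed form F = alpha (I - (1-alpha) W)^-1,
# whose entry F[i, j] is the walk mass starting at node i that ends at
# node j. Convention used throughout: the influence OF node j ON node i is
# the mass that starts at j and arrives at i, i.e. F[j, i]. Consequently
# label-to-cell influence (what drives cell labeling) is the block
# t(F[labels, cells]): walks begin at a label node, which normalizes the
# influence by label degree so that labels anchored to more cells do not
# automatically dominate.

#' Row-normalized walk matrix
#'
#' Computes W = D^-1 A where D is the diagonal of row sums of the
#' adjacency. Zero-degree nodes are given a unit self-loop before
#' normalization (their row becomes a standard basis vector) so that node
#' indexing stays aligned with the input cells; such nodes are reported in
#' a warning.
#'
#' @param graph a `combined_graph`, or a plain nonnegative symmetric
#'   adjacency matrix.
#' @return dense q x q row-stochastic matrix, dimnames preserved, with the
#'   graph's node bookkeeping attached as attributes `cell_ids` / `labels`
#'   when available.
#' @export
walk_matrix <- function(graph) {
  cell_ids <- labels <- NULL
  if (inherits(graph, "combined_graph")) {
    cell_ids <- graph$cell_ids
    labels <- graph$labels
    a <- graph$adjacency
  } else {
    a <- graph
  }
  sparse <- is(a, "Matrix")
  if (!sparse) a <- as.matrix(a)
  if (any((if (sparse) a@x else a) < 0)) stop("adjacency must be nonnegative")
  d <- if (sparse) Matrix::rowSums(a) else rowSums(a)
  zero <- which(d == 0)
  if (length(zero)) {
    nm <- rownames(a)
    warning("zero-degree node(s) given self-loops: ",
            paste(if (is.null(nm)) zero else nm[zero], collapse = ", "))
    a[cbind(zero, zero)] <- 1
    d[zero] <- 1
  }
  w <- if (sparse) Matrix::Diagonal(x = 1 / d) %*% a else a / d
  if (sparse) dimnames(w) <- dimnames(a)
  attr(w, "cell_ids") <- cell_ids
  attr(w, "labels") <- labels
  w
}

#' Closed-form influence matrix of the restart walk
#'
#' Solves F = alpha (I - (1-alpha) W)^-1 by LU-factorized linear solves
#' (never by power iteration). For graphs up to `dense_cap` nodes the full
#' dense q x q matrix is materialized; above the cap only the requested
#' `columns` are solved for via sparse LU (the applications need the label
#' columns plus cell subsets, not all of F).
#'
#' Because W is row-stochastic, each row of F sums to exactly 1 and every
#' diagonal entry is at least alpha.
#'
#' @param W a walk matrix from [walk_matrix()].
#' @param alpha restart probability in (0, 1); default 0.5, the midpoint of
#'   the 0.4-0.6 range in which diffusion encodes graph structure stably.
#' @param columns optional node indices: compute only these columns of F.
#' @param dense_cap node-count threshold above which the full matrix is not
#'   materialized unless `columns` is given.
#' @return an `influence_matrix`: list(F, alpha, cell_ids, labels). When
#'   `columns` is given, F has q rows and `length(columns)` columns.
#' @export
influence_matrix <- function(W, alpha = 0.5, columns = NULL,
                             dense_cap = 20000) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  q <- nrow(W)
  cell_ids <- attr(W, "cell_ids")
  labels <- attr(W, "labels")
  if (is.null(columns)) {
    if (q > dense_cap)
      stop(sprintf(
        "graph has %d nodes (> dense_cap %d); pass `columns` for the needed blocks",
        q, dense_cap))
    m <- diag(q) - (1 - alpha) * as.matrix(W)
    f <- alpha * solve(m)
  } else if (is(W, "Matrix") && !is.matrix(W)) {
    # sparse LU, one solve per requested column; dense q x q never built
    m <- Matrix::Diagonal(q) - (1 - alpha) * W
    rhs <- Matrix::sparseMatrix(i = columns, j = seq_along(columns), x = 1,
                                dims = c(q, length(columns)))
    f <- as.matrix(alpha * Matrix::solve(m, rhs))
    colnames(f) <- rownames(W)[columns]
  } else {
    m <- diag(q) - (1 - alpha) * as.matrix(W)
    f <- alpha * solve(m, diag(q)[, columns, drop = FALSE])
    colnames(f) <- rownames(W)[columns]
  }
  rownames(f) <- rownames(W)
  if (is.null(columns)) colnames(f) <- colnames(W)
  rs <- rowSums(f)
  if (is.null(columns) && max(abs(rs - 1)) > 1e-8)
    stop("influence matrix rows do not sum to 1: solver failure")
  structure(list(F = f, alpha = alpha, cell_ids = cell_ids, labels = labels),
            class = "influence_matrix")
}

#' @export
print.influence_matrix <- function(x, ...) {
  cat(sprintf("influence_matrix: %d x %d, alpha = %g (%d cells, %d labels)\n",
              nrow(x$F), ncol(x$F), x$alpha,
              length(x$cell_ids), length(x$labels)))
  invisible(x)
}

# block accessors; rely on the cells-first node order
.cell_idx <- function(x) seq_along(x$cell_ids)
.label_idx <- function(x) length(x$cell_ids) + seq_along(x$labels)

#' Influence-matrix blocks
#'
#' Named blocks under the convention that the influence of node j on node i
#' is the walk mass starting at j that ends at i (`F[j, i]` for the
#' row-stochastic F): `label_to_cell` (n x m) drives cell labeling,
#' `cell_to_label` (m x n) maps bulk signal to labels, `label_to_label`
#' (m x m) drives label clustering, and `cell_to_cell` (n x n) is a
#' label-aware cell clustering. Entry `[i, j]` of each block is the
#' influence of source j (second name) on target i (first name).
#'
#' @param x an `influence_matrix` (full, not column-subset).
#' @return the requested dense block with dimnames.
#' @export
label_to_cell <- function(x) t(x$F[.label_idx(x), .cell_idx(x), drop = FALSE])

#' @rdname label_to_cell
#' @export
cell_to_label <- function(x) t(x$F[.cell_idx(x), .label_idx(x), drop = FALSE])

#' @rdname label_to_cell
#' @export
label_to_label <- function(x) t(x$F[.label_idx(x), .label_idx(x), drop = FALSE])

#' @rdname label_to_cell
#' @export
cell_to_cell <- function(x) t(x$F[.cell_idx(x), .cell_idx(x), drop = FALSE])

#' Truncated Neumann-series approximation of the influence matrix
#'
#' Computes alpha * sum_{k=0}^{k_max} (1-alpha)^k W^k. The truncation error
#' is bounded by (1-alpha)^(k_max+1) in max norm. This is a test oracle for
#' the closed-form solve, not a production path.
#'
#' @param W walk matrix.
#' @param alpha restart probability.
#' @param k_max number of walk steps retained (>= 0).
#' @return dense matrix approximation of F.
#' @export
influence_series_oracle <- function(W, alpha = 0.5, k_max = 50) {
  if (k_max < 0) stop("k_max must be >= 0")
  W <- as.matrix(W)
  q <- nrow(W)
  term <- diag(q)
  acc <- diag(q)
  for (k in seq_len(k_max)) {
    term <- (1 - alpha) * (term %*% W)
    acc <- acc + term
  }
  alpha * acc
}
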