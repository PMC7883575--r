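# Tuning the label edge weight s by cell homogeneity.
#
# Cell homogeneity is the natural log of the ratio of the pooled median
# within-group cell-to-cell influence to the pooled median between-group
# influence. It is computed directly from F, so the label edge weight can
# be tuned without held-out truth: the groups default to the top-label
# assignment produced at that same s.

#' Assign each cell its maximum-influence label
#'
#' Cell i receives the label with the largest label-to-cell influence
#' `F[i, label]`. Exact ties break deterministically to the
#' earliest label; the number of tied cells is reported via the
#' `n_ties` attribute.
#'
#' @param F an `influence_matrix` with at least one label.
#' @return character vector of per-cell labels (names = cell ids), with
#'   attribute `n_ties`.
#' @export
assign_top_labels <- function(F) {
  ltc <- label_to_cell(F)
  if (ncol(ltc) < 1) stop("no labels in influence matrix")
  top <- max.col(ltc, ties.method = "first")
  rowmax <- ltc[cbind(seq_len(nrow(ltc)), top)]
  n_ties <- sum(rowSums(ltc == rowmax) > 1)
  out <- F$labels[top]
  names(out) <- F$cell_ids
  attr(out, "n_ties") <- n_ties
  out
}

#' Cell homogeneity of an influence matrix
#'
#' Pools every ordered off-diagonal cell-to-cell influence F[i, j] (i != j)
#' into within-group pairs (group(i) == group(j)) and between-group pairs,
#' and returns `ln(median(within) / median(between))`. A value of 0 means
#' within-type and between-type influence are indistinguishable; larger
#' values mean better separation of the groups.
#'
#' Undefined (fatal) unless at least two groups each hold >= 2 cells, since
#' otherwise one of the pools is empty.
#'
#' @param F an `influence_matrix`.
#' @param groups per-cell group labels (e.g. from [assign_top_labels()] or
#'   simulation truth), length = number of cells.
#' @return a `homogeneity_result`: list(value, n_within_pairs,
#'   n_between_pairs, assignments).
#' @export
cell_homogeneity <- function(F, groups) {
  cc <- cell_to_cell(F)
  n <- nrow(cc)
  groups <- as.character(groups)
  if (length(groups) != n)
    stop("groups must have one entry per cell")
  tab <- table(groups)
  if (sum(tab >= 2) < 2)
    stop("homogeneity undefined: need >= 2 groups with >= 2 cells each")
  same <- outer(groups, groups, "==")
  off <- !diag(n)
  within <- cc[same & off]
  between <- cc[!same]
  structure(list(value = log(median(within) / median(between)),
                 n_within_pairs = length(within),
                 n_between_pairs = length(between),
                 assignments = groups),
            class = "homogeneity_result")
}

#' @export
print.homogeneity_result <- function(x, ...) {
  cat(sprintf("cell homogeneity: %.4f (%d within, %d between pairs)\n",
              x$value, x$n_within_pairs, x$n_between_pairs))
  invisible(x)
}

#' Grid search over the label edge weight
#'
#' For each s in `grid`: assemble the combined graph, diffuse, assign top
#' labels, and compute cell homogeneity. `best_s` is the grid argmax of
#' homogeneity, ties broken toward the smaller s. By default the grouping
#' used for homogeneity is the top-label assignment produced at that s;
#' pass `groups` (e.g. simulation truth) to score against fixed labels
#' instead.
#'
#' @param cell_edges symmetric cell similarity matrix.
#' @param label_edges labels x cells weight matrix.
#' @param grid strictly positive label edge weights to try; the defaults
#'   used in practice are powers of 10, 1e-2..1e4 for real data and
#'   1e-4..1e-1 for simulated data.
#' @param alpha restart probability.
#' @param groups optional fixed per-cell groups for homogeneity.
#' @param ambiguity_quantile quantile for [flag_ambiguous()] used to count
#'   ambiguous cells per grid point.
#' @return a `tuning_table` data.frame with columns s, homogeneity,
#'   n_ambiguous and attribute `best_s`.
#' @export
tune_label_weight <- function(cell_edges, label_edges,
                              grid = 10^seq(-2, 4), alpha = 0.5,
                              groups = NULL, ambiguity_quantile = 0.10) {
  if (length(grid) == 0) stop("empty grid")
  if (any(grid <= 0)) stop("label edge weights must be positive")
  grid <- sort(grid)
  rows <- lapply(grid, function(s) {
    tryCatch({
      g <- assemble(cell_edges, label_edges, s)
      f <- influence_matrix(walk_matrix(g), alpha = alpha)
      grp <- if (is.null(groups)) assign_top_labels(f) else groups
      h <- cell_homogeneity(f, grp)
      n_amb <- if (length(f$labels) >= 2) {
        sc <- label_scores(f)
        sum(flag_ambiguous(sc, quantile = ambiguity_quantile))
      } else NA_integer_
      data.frame(s = s, homogeneity = h$value, n_ambiguous = n_amb)
    }, error = function(e) {
      warning(sprintf("s = %g failed: %s", s, conditionMessage(e)))
      NULL
    })
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stop("tuning failed at every grid point")
  out <- do.call(rbind, rows)
  best <- out$s[which.max(out$homogeneity)]  # first max = smallest s on ties
  attr(out, "best_s") <- best
  class(out) <- c("tuning_table", "data.frame")
  out
}

#' Best label edge weight of a tuning table
#' @param x a `tuning_table`.
#' @export
best_edge_weight <- function(x) attr(x, "best_s")
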