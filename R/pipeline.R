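# End-to-end conveniences tying the modules together.

#' Assemble, normalize, and diffuse in one call
#'
#' @param cell_edges symmetric cell-cell similarity matrix.
#' @param label_edges labels x cells weight matrix.
#' @param s label edge weight.
#' @param alpha restart probability.
#' @return an `influence_matrix`.
#' @export
run_diffusion <- function(cell_edges, label_edges, s, alpha = 0.5) {
  influence_matrix(walk_matrix(assemble(cell_edges, label_edges, s)),
                   alpha = alpha)
}

#' Fraction of correctly labeled cells
#'
#' @param assignments per-cell labels (e.g. from [assign_top_labels()]).
#' @param truth per-cell true types, same length/order.
#' @param subset optional logical or integer index of cells to score
#'   (e.g. only the initially unlabeled cells).
#' @return fraction in `[0, 1]`.
#' @export
labeling_accuracy <- function(assignments, truth, subset = NULL) {
  if (length(assignments) != length(truth))
    stop("assignments and truth lengths differ")
  if (!is.null(subset)) {
    assignments <- assignments[subset]
    truth <- truth[subset]
  }
  if (length(truth) == 0) stop("no cells to score")
  mean(assignments == truth)
}
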