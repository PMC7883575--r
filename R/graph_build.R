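# Construction of the combined cell + label network.
#
# Three edge families: cell-to-cell (Jaccard similarity of binarized
# accessibility), label-to-cell (marker-gene-derived), and the assembled
# block adjacency in which the label-to-cell block is scaled by the single
# label edge weight s. Label-label edges are always zero: labels talk to
# each other only through cells.

#' Jaccard similarity between cells
#'
#' Binarizes accessibility (count > 0) and computes, for every pair of
#' cells, the Jaccard index of their accessible feature sets. The diagonal
#' is forced to zero: self-information enters the walk only through the
#' restart. Cells with empty support get similarity 0 to everything
#' (an uninformative cell should not attract walks).
#'
#' @param matrix a `cell_matrix` with `feature_kind` "peak" or "bin", or a
#'   plain (sparse) nonnegative matrix with cells in rows.
#' @return symmetric dense n x n matrix in `[0, 1]`, zero diagonal,
#'   dimnames = cell ids when available.
#' @export
jaccard_cell_similarity <- function(matrix) {
  ids <- NULL
  if (inherits(matrix, "cell_matrix")) {
    if (matrix$feature_kind == "gene")
      stop("Jaccard similarity is defined for peak/bin matrices")
    ids <- matrix$cell_ids
    matrix <- matrix$values
  }
  b <- .as_dgc(matrix > 0)
  inter <- as.matrix(Matrix::tcrossprod(b))
  supp <- Matrix::rowSums(b)
  uni <- outer(supp, supp, "+") - inter
  w <- inter / uni
  w[uni == 0] <- 0
  diag(w) <- 0
  if (!is.null(ids)) dimnames(w) <- list(ids, ids)
  w
}

#' Strand-aware promoter + gene-body windows
#'
#' For each gene, the union of the gene body and a promoter window of
#' `upstream_bp` ending at the TSS (upstream of `start` on `+`, of `end`
#' on `-`), clipped at coordinate 0. Since the promoter abuts the body the
#' union is one interval per gene.
#'
#' @param annotation a `gene_annotation`.
#' @param upstream_bp promoter length in bp upstream of the TSS
#'   (default 2000).
#' @return a `genomic_intervals` set, one interval per gene, named by gene.
#' @export
promoter_windows <- function(annotation, upstream_bp = 2000) {
  if (upstream_bp < 0) stop("upstream_bp must be >= 0")
  start <- ifelse(annotation$strand == "+",
                  pmax(0, annotation$start - upstream_bp), annotation$start)
  end <- ifelse(annotation$strand == "+",
                annotation$end, annotation$end + upstream_bp)
  genomic_intervals(annotation$chrom, start, end,
                    name = annotation$gene, strand = annotation$strand)
}

# marker weight: logFC where present, 1 where absent
marker_weights <- function(markers) {
  ifelse(is.na(markers$logFC), 1, markers$logFC)
}

#' Label-to-cell edge weights from a cell-by-peak matrix
#'
#' For each label l and cell c:
#' weight(l, c) = sum over marker genes g of l of
#'   logFC(g) * (# of c's accessible peaks overlapping g's body+promoter)
#'             / (total accessible peaks of c).
#' Cells with no accessible peaks get weight 0 everywhere. Marker genes
#' absent from the annotation are skipped with a warning; a label whose
#' markers are all missing is a fatal error.
#'
#' @param matrix a `cell_matrix` with peak/bin features carrying coordinates.
#' @param markers a `marker_set`.
#' @param annotation a `gene_annotation`.
#' @param upstream_bp promoter window size (default 2000).
#' @return m x n matrix (labels x cells), rownames = labels,
#'   colnames = cell ids.
#' @export
label_edges_from_peaks <- function(matrix, markers, annotation,
                                   upstream_bp = 2000) {
  if (!inherits(matrix, "cell_matrix") || matrix$feature_kind == "gene")
    stop("matrix must be a peak/bin cell_matrix")
  labels <- marker_labels(markers)
  present <- markers$gene %in% annotation$gene
  if (any(!present)) {
    missing_by_label <- tapply(!present, markers$label, all)
    dead <- names(missing_by_label)[missing_by_label]
    if (length(dead))
      stop("all marker genes missing from annotation for label(s): ",
           paste(dead, collapse = ", "))
    warning(sprintf("%d marker gene(s) missing from annotation; skipped",
                    sum(!present)))
  }
  mk <- markers[present, , drop = FALSE]
  ann <- annotation[match(unique(mk$gene), annotation$gene), , drop = FALSE]
  windows <- promoter_windows(ann, upstream_bp)

  b <- .as_dgc(matrix$values > 0)                         # n x p binary
  hits <- GenomicRanges::findOverlaps(gis_to_granges(matrix$features),
                                      gis_to_granges(windows),
                                      ignore.strand = TRUE)
  # p x G indicator: peak j overlaps window of gene g
  ind <- Matrix::sparseMatrix(i = S4Vectors::queryHits(hits),
                              j = S4Vectors::subjectHits(hits), x = 1,
                              dims = c(ncol(b), nrow(windows)))
  counts <- b %*% ind                               # n x G overlap counts
  n_acc <- Matrix::rowSums(b)
  w <- matrix(0, nrow = length(labels), ncol = nrow(b),
              dimnames = list(labels, matrix$cell_ids))
  lfc <- marker_weights(mk)
  gidx <- match(mk$gene, windows$name)
  for (l in labels) {
    sel <- mk$label == l
    v <- Matrix::rowSums(counts[, gidx[sel], drop = FALSE] %*%
                           Matrix::Diagonal(x = lfc[sel]))
    w[l, ] <- ifelse(n_acc > 0, v / n_acc, 0)
  }
  w
}

#' Label-to-cell edge weights from a cell-by-gene score matrix
#'
#' Each cell's gene scores are normalized to sum to one; the weight of
#' label l on cell c is the logFC-weighted sum of the normalized scores of
#' l's marker genes. Marker genes absent from the matrix are skipped with a
#' warning (a label left with no present marker yields a zero row, which
#' [assemble()] rejects).
#'
#' @param matrix a `cell_matrix` with `feature_kind = "gene"`.
#' @param markers a `marker_set`.
#' @return m x n matrix (labels x cells).
#' @export
label_edges_from_genescores <- function(matrix, markers) {
  if (!inherits(matrix, "cell_matrix") || matrix$feature_kind != "gene")
    stop("matrix must be a gene-score cell_matrix")
  labels <- marker_labels(markers)
  present <- markers$gene %in% matrix$features
  if (any(!present))
    warning(sprintf("%d marker gene(s) absent from matrix; skipped",
                    sum(!present)))
  mk <- markers[present, , drop = FALSE]
  tot <- Matrix::rowSums(matrix$values)
  norm <- matrix$values / ifelse(tot > 0, tot, 1)    # all-zero cell stays zero
  lfc <- marker_weights(mk)
  gidx <- match(mk$gene, matrix$features)
  w <- matrix(0, nrow = length(labels), ncol = nrow(norm),
              dimnames = list(labels, matrix$cell_ids))
  for (l in labels) {
    sel <- mk$label == l
    if (!any(sel)) next
    w[l, ] <- as.numeric(norm[, gidx[sel], drop = FALSE] %*% lfc[sel])
  }
  w
}

#' Assemble the combined cell + label graph
#'
#' Builds the symmetric block adjacency over q = n_cells + n_labels nodes
#' (cells first, labels last):
#' `A[cells, cells]` = cell similarities, `A[cells, labels]` = s * t(L),
#' `A[labels, labels]` = 0, where L is the label-to-cell weight matrix and
#' s the label edge weight trading external label trust against intrinsic
#' cell similarity.
#'
#' By default (`normalize_ratio = TRUE`) s is interpreted as the ratio of
#' total label-edge weight to total cell-edge weight: the label block is
#' multiplied by `s * sum(cell_edges) / sum(label_edges)`. This makes the
#' meaning of any given s independent of the scale of the similarity
#' matrix, so the standard tuning grids span the same regimes (de novo
#' clustering at low s, direct label assignment at high s) on any dataset.
#' With `normalize_ratio = FALSE`, s multiplies the label weights as-is.
#'
#' @param cell_edges symmetric nonnegative n x n matrix, zero diagonal.
#' @param label_edges nonnegative m x n matrix (labels x cells); every
#'   label row must have at least one positive entry.
#' @param s positive scalar label edge weight.
#' @param cell_ids,labels optional node names; defaults taken from dimnames.
#' @param normalize_ratio interpret s as a label-mass/cell-mass ratio
#'   (default) rather than a raw multiplier.
#' @return a `combined_graph`: list(adjacency, s, cell_ids, labels).
#' @export
assemble <- function(cell_edges, label_edges, s,
                     cell_ids = NULL, labels = NULL,
                     normalize_ratio = TRUE) {
  if (!is.numeric(s) || length(s) != 1 || s <= 0)
    stop("label edge weight s must be a positive scalar")
  n <- nrow(cell_edges)
  m <- nrow(label_edges)
  if (ncol(cell_edges) != n) stop("cell_edges must be square")
  if (ncol(label_edges) != n)
    stop("label_edges columns must match number of cells")
  if (any(cell_edges < 0) || any(label_edges < 0))
    stop("negative edge weights")
  if (max(abs(cell_edges - t(cell_edges))) > 1e-12)
    stop("cell_edges must be symmetric")
  dead <- which(apply(label_edges, 1, function(r) all(r == 0)))
  if (length(dead)) {
    nm <- rownames(label_edges)
    stop("label(s) with no positive cell edge: ",
         paste(if (is.null(nm)) dead else nm[dead], collapse = ", "))
  }
  if (is.null(cell_ids))
    cell_ids <- rownames(cell_edges) %||% paste0("cell", seq_len(n))
  if (is.null(labels))
    labels <- rownames(label_edges) %||% paste0("label", seq_len(m))
  fac <- if (normalize_ratio) s * sum(cell_edges) / sum(label_edges) else s
  a <- matrix(0, n + m, n + m, dimnames = list(c(cell_ids, labels),
                                               c(cell_ids, labels)))
  a[1:n, 1:n] <- as.matrix(cell_edges)
  a[1:n, n + (1:m)] <- fac * t(label_edges)
  a[n + (1:m), 1:n] <- fac * label_edges
  structure(list(adjacency = a, s = s, cell_ids = cell_ids, labels = labels),
            class = "combined_graph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.combined_graph <- function(x, ...) {
  cat(sprintf("combined_graph: %d cells + %d labels, s = %g\n",
              length(x$cell_ids), length(x$labels), x$s))
  invisible(x)
}
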