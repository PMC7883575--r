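#' @importFrom methods as is
#' @importFrom stats median quantile sd cor rlnorm rgamma rmultinom runif setNames p.adjust hclust dist as.dendrogram
#' @importFrom utils read.table write.table head
NULL

# ---- Genomic interval sets -------------------------------------------------
# Intervals are kept in BED convention throughout: 0-based, half-open.
# Overlap computations convert to 1-based closed IRanges via gis_to_granges().

#' Construct a genomic interval set
#'
#' A thin validated data.frame of genomic intervals in BED convention
#' (0-based, half-open).
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start,end integer vectors; `0 <= start < end` for every record.
#' @param name optional interval names.
#' @param strand optional strand, each element one of `"+"`, `"-"`, `"."`.
#' @return A `data.frame` with class `genomic_intervals` and columns
#'   `chrom`, `start`, `end`, `name`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL, strand = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- length(chrom)
  if (length(start) != n || length(end) != n)
    stop("chrom, start, end must have equal length")
  if (any(is.na(chrom)) || any(!nzchar(chrom)))
    stop("chrom names must be non-empty")
  if (any(start < 0)) stop("negative start coordinate")
  if (any(start >= end)) stop("interval with start >= end (BED half-open requires start < end)")
  if (is.null(name)) name <- rep(NA_character_, n)
  if (is.null(strand)) strand <- rep(".", n)
  if (!all(strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  out <- data.frame(chrom = chrom, start = start, end = end,
                    name = as.character(name), strand = strand,
                    stringsAsFactors = FALSE)
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Convert an interval set to GRanges (1-based closed) for overlap work
#' @param x a `genomic_intervals` data.frame (BED convention).
#' @return a `GenomicRanges::GRanges` object.
#' @keywords internal
gis_to_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = ifelse(x$strand == ".", "*", x$strand))
}

#' Read a BED3/BED6 file into a genomic interval set
#'
#' @param path path to a tab-separated BED file (no header).
#' @return a `genomic_intervals` data.frame.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#",
                   colClasses = "character")
  if (ncol(df) < 3) stop("BED file needs at least 3 columns: ", path)
  genomic_intervals(
    chrom = df[[1]], start = as.numeric(df[[2]]), end = as.numeric(df[[3]]),
    name = if (ncol(df) >= 4) df[[4]] else NULL,
    strand = if (ncol(df) >= 6) df[[6]] else NULL)
}

#' Write a genomic interval set as BED
#' @param x a `genomic_intervals` data.frame.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  out <- data.frame(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
                    format(x$end, scientific = FALSE, trim = TRUE))
  if (!all(is.na(x$name))) {
    out$name <- ifelse(is.na(x$name), ".", x$name)
    out$score <- 0
    out$strand <- x$strand
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- Cell-by-feature matrices ---------------------------------------------

# coerce any base/Matrix numeric or logical matrix to dgCMatrix
.as_dgc <- function(x) {
  if (is.matrix(x)) x <- Matrix::Matrix(x, sparse = TRUE)
  as(as(as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

#' Construct a cell-by-feature count matrix
#'
#' The central container for scATAC-seq data: a sparse nonnegative matrix
#' with rows = cells and columns = features (peaks, genomic bins, or genes).
#'
#' @param values sparse or dense nonnegative numeric matrix, cells in rows.
#' @param cell_ids unique character vector, one per row.
#' @param features either a `genomic_intervals` data.frame (for
#'   `feature_kind` "peak"/"bin") or a character vector of gene symbols
#'   (for "gene").
#' @param feature_kind one of `"peak"`, `"bin"`, `"gene"`.
#' @return a `cell_matrix` object (list with the four fields above).
#' @export
cell_matrix <- function(values, cell_ids, features,
                        feature_kind = c("peak", "bin", "gene")) {
  feature_kind <- match.arg(feature_kind)
  values <- .as_dgc(values)
  cell_ids <- as.character(cell_ids)
  if (nrow(values) != length(cell_ids))
    stop(sprintf("matrix has %d rows but %d cell ids", nrow(values),
                 length(cell_ids)))
  if (anyDuplicated(cell_ids)) stop("duplicate cell barcodes")
  n_feat <- if (feature_kind == "gene") length(features) else nrow(features)
  if (ncol(values) != n_feat)
    stop(sprintf("matrix has %d columns but %d features", ncol(values), n_feat))
  if (any(values@x < 0)) stop("negative entries in count matrix")
  if (feature_kind == "gene") {
    features <- as.character(features)
  } else if (!inherits(features, "genomic_intervals")) {
    stop("peak/bin features must be a genomic_intervals object")
  }
  structure(list(values = values, cell_ids = cell_ids, features = features,
                 feature_kind = feature_kind),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("cell_matrix: %d cells x %d %s features, %d nonzeros\n",
              nrow(x$values), ncol(x$values), x$feature_kind,
              length(x$values@x)))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$values)

#' Read a MatrixMarket cell matrix triplet
#'
#' Reads the cellranger-atac-style triplet: a MatrixMarket `.mtx` file plus
#' a barcodes file (one cell ID per line) and a features file (BED for
#' peaks/bins, one gene symbol per line for genes). The matrix on disk may
#' be stored cells-by-features or features-by-cells; the orientation is
#' resolved by matching the declared dimensions against the barcode and
#' feature counts. A square matrix is ambiguous and requires an explicit
#' `transpose` flag.
#'
#' @param mtx_path path to MatrixMarket coordinate file.
#' @param barcodes_path one barcode per line.
#' @param features_path BED file (peak/bin) or one gene per line (gene).
#' @param feature_kind `"peak"`, `"bin"`, or `"gene"`.
#' @param transpose `NA` (auto-detect), `TRUE` (file is features x cells),
#'   or `FALSE` (file is cells x features).
#' @return a `cell_matrix`.
#' @export
read_cell_matrix <- function(mtx_path, barcodes_path, features_path,
                             feature_kind = c("peak", "bin", "gene"),
                             transpose = NA) {
  feature_kind <- match.arg(feature_kind)
  m <- Matrix::readMM(mtx_path)
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  if (anyDuplicated(barcodes)) stop("duplicate cell barcodes in ", barcodes_path)
  features <- if (feature_kind == "gene") {
    g <- readLines(features_path); g[nzchar(g)]
  } else {
    read_bed(features_path)
  }
  n_cells <- length(barcodes)
  n_feat <- if (feature_kind == "gene") length(features) else nrow(features)
  if (is.na(transpose)) {
    as_is <- nrow(m) == n_cells && ncol(m) == n_feat
    flipped <- ncol(m) == n_cells && nrow(m) == n_feat
    if (as_is && flipped)
      stop("square matrix: orientation ambiguous; pass transpose=TRUE/FALSE")
    if (!as_is && !flipped)
      stop(sprintf(
        "matrix is %d x %d but there are %d barcodes and %d features (no orientation fits)",
        nrow(m), ncol(m), n_cells, n_feat))
    transpose <- flipped
  }
  if (transpose) m <- Matrix::t(m)
  if (nrow(m) != n_cells || ncol(m) != n_feat)
    stop(sprintf("matrix is %d x %d after orientation but expected %d x %d",
                 nrow(m), ncol(m), n_cells, n_feat))
  cell_matrix(m, barcodes, features, feature_kind)
}

#' Write a cell matrix as a MatrixMarket triplet
#'
#' Inverse of [read_cell_matrix()]; writes `<prefix>.mtx`,
#' `<prefix>.barcodes.tsv` and `<prefix>.features.{bed,txt}`.
#'
#' @param x a `cell_matrix`.
#' @param prefix output path prefix.
#' @return paths of the three files, invisibly.
#' @export
write_cell_matrix <- function(x, prefix) {
  mtx <- paste0(prefix, ".mtx")
  bar <- paste0(prefix, ".barcodes.tsv")
  Matrix::writeMM(x$values, mtx)
  writeLines(x$cell_ids, bar)
  if (x$feature_kind == "gene") {
    feat <- paste0(prefix, ".features.txt")
    writeLines(x$features, feat)
  } else {
    feat <- paste0(prefix, ".features.bed")
    write_bed(x$features, feat)
  }
  invisible(c(mtx, bar, feat))
}

# ---- Markers ---------------------------------------------------------------

#' Construct a marker set
#'
#' Cell-type labels with their marker genes and optional expression
#' log-fold changes. Edge weighting multiplies by logFC, so logFC must be
#' positive (markers are genes up-regulated IN the label).
#'
#' @param label,gene character vectors of equal length.
#' @param logFC optional positive numeric vector (NA allowed per entry;
#'   absent logFC means weight 1 downstream).
#' @return a `marker_set` data.frame with a `labels` attribute holding
#'   labels in first-appearance order.
#' @export
marker_set <- function(label, gene, logFC = NULL) {
  label <- as.character(label); gene <- as.character(gene)
  if (length(label) != length(gene)) stop("label and gene lengths differ")
  if (is.null(logFC)) logFC <- rep(NA_real_, length(label))
  logFC <- as.numeric(logFC)
  if (any(!is.na(logFC) & logFC <= 0))
    stop("non-positive logFC: markers must be up-regulated in their label")
  if (anyDuplicated(paste0(label, "\r", gene)))
    stop("duplicate (label, gene) marker pairs")
  out <- data.frame(label = label, gene = gene, logFC = logFC,
                    stringsAsFactors = FALSE)
  attr(out, "labels") <- unique(label)
  class(out) <- c("marker_set", "data.frame")
  out
}

#' Labels of a marker set, in first-appearance order
#' @param markers a `marker_set`.
#' @export
marker_labels <- function(markers) attr(markers, "labels")

#' Read a marker table
#'
#' Expects a TSV with header columns `label`, `gene` and optionally `logFC`.
#'
#' @param tsv_path path to the marker TSV.
#' @return a `marker_set`.
#' @export
read_markers <- function(tsv_path) {
  df <- read.table(tsv_path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  if (!all(c("label", "gene") %in% names(df)))
    stop("marker TSV must have 'label' and 'gene' columns")
  marker_set(df$label, df$gene,
             logFC = if ("logFC" %in% names(df)) df$logFC else NULL)
}

# ---- Gene annotation -------------------------------------------------------

#' Construct a gene annotation table
#'
#' @param gene unique gene symbols.
#' @param chrom,start,end BED-convention coordinates of the gene body.
#' @param strand `"+"` or `"-"` for every gene (required: the TSS and the
#'   promoter window are strand-dependent).
#' @return a `gene_annotation` data.frame with a derived `tss` column
#'   (BED coordinate of the transcription start site: `start` on `+`,
#'   `end` on `-`).
#' @export
gene_annotation <- function(gene, chrom, start, end, strand) {
  gene <- as.character(gene)
  strand <- as.character(strand)
  if (any(!strand %in% c("+", "-")))
    stop("every gene needs strand '+' or '-' (TSS is strand-dependent)")
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0) || any(start >= end)) stop("invalid gene coordinates")
  if (anyDuplicated(gene)) {
    # keep the longest interval per duplicated gene
    len <- end - start
    ord <- order(-len)
    keep <- ord[!duplicated(gene[ord])]
    keep <- sort(keep)
    warning(sprintf("%d duplicate gene name(s); keeping longest interval each",
                    sum(duplicated(gene))))
    gene <- gene[keep]; chrom <- chrom[keep]
    start <- start[keep]; end <- end[keep]; strand <- strand[keep]
  }
  out <- data.frame(gene = gene, chrom = as.character(chrom),
                    start = start, end = end, strand = strand,
                    tss = ifelse(strand == "+", start, end),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_annotation", "data.frame")
  out
}

#' Read gene annotation from BED6 or a 5-column TSV
#'
#' Accepts either a BED6 file (4th column = gene symbol, 6th = strand) or a
#' header TSV with columns `gene`, `chrom`, `start`, `end`, `strand`.
#' Strand is mandatory; genes on strand `"."` are rejected because the TSS
#' cannot be derived.
#'
#' @param path input path.
#' @return a `gene_annotation`.
#' @export
read_gene_annotation <- function(path) {
  first <- readLines(path, n = 1)
  fields <- strsplit(first, "\t", fixed = TRUE)[[1]]
  if ("gene" %in% fields && "strand" %in% fields) {
    df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    gene_annotation(df$gene, df$chrom, df$start, df$end, df$strand)
  } else {
    bed <- read_bed(path)
    if (all(is.na(bed$name))) stop("BED gene annotation needs a name column")
    if (any(bed$strand == "."))
      stop("every gene needs strand '+' or '-' (TSS is strand-dependent)")
    gene_annotation(bed$name, bed$chrom, bed$start, bed$end, bed$strand)
  }
}

# ---- Output writers --------------------------------------------------------

#' Write per-cell label scores as TSV
#'
#' One row per cell: `cell_id`, one column per label, `top_label`,
#' `ambiguous`.
#'
#' @param scores a `label_score_matrix` (see [label_scores()]).
#' @param path output path.
#' @export
write_label_scores <- function(scores, path) {
  if (!inherits(scores, "label_score_matrix"))
    stop("scores must be a label_score_matrix")
  if (ncol(scores$scores) == 0) stop("empty label set")
  df <- data.frame(cell_id = rownames(scores$scores),
                   as.data.frame(scores$scores, check.names = FALSE),
                   top_label = scores$top_label,
                   ambiguous = scores$ambiguous,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a label dendrogram as Newick
#'
#' @param tree an `hclust` object over labels (see [cluster_labels()]).
#' @param path output path.
#' @export
write_dendrogram <- function(tree, path) {
  if (!inherits(tree, "hclust")) stop("tree must be an hclust object")
  if (length(tree$labels) < 2) stop("need at least 2 labels to write a tree")
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
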