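# Applications of the influence matrix: fuzzy cell labeling with ambiguity
# calls, label clustering, bulk-region-to-label mapping, and the annotation
# statistics built on top of them (progression scores, region-score
# correlation, permutation bimodality, nearest-gene enrichment).

#' Normalized per-cell label scores
#'
#' Takes the label-to-cell block of F, z-scores each label column across
#' cells (sample standard deviation; a column with zero spread maps to all
#' zeros so label indices stay stable), then rescales each cell's row to a
#' maximum of one (rows whose maximum is <= 0 are left as-is). The result
#' is a "fuzzy" labeling: a cell may score highly for several labels.
#'
#' @param F an `influence_matrix` with >= 2 cells.
#' @return a `label_score_matrix`: list(scores [n x m], top_label,
#'   second_label, gap, ambiguous). `ambiguous` is filled by
#'   [flag_ambiguous()]; here it is initialized to FALSE.
#' @export
label_scores <- function(F) {
  raw <- label_to_cell(F)
  if (nrow(raw) < 2) stop("z-scores undefined with a single cell")
  z <- apply(raw, 2, function(col) {
    s <- sd(col)
    if (is.na(s) || s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  z <- matrix(z, nrow = nrow(raw), dimnames = dimnames(raw))
  rowmax <- apply(z, 1, max)
  sc <- z / ifelse(rowmax > 0, rowmax, 1)
  m <- ncol(sc)
  ord <- if (m == 1) matrix(1L, nrow(sc), 1)
         else t(apply(sc, 1, order, decreasing = TRUE))
  top <- colnames(sc)[ord[, 1]]
  second <- if (m >= 2) colnames(sc)[ord[, 2]] else rep(NA_character_, nrow(sc))
  gap <- if (m >= 2) sc[cbind(seq_len(nrow(sc)), ord[, 1])] -
    sc[cbind(seq_len(nrow(sc)), ord[, 2])] else rep(NA_real_, nrow(sc))
  structure(list(scores = sc, top_label = setNames(top, rownames(sc)),
                 second_label = second, gap = gap,
                 ambiguous = rep(FALSE, nrow(sc))),
            class = "label_score_matrix")
}

#' @export
print.label_score_matrix <- function(x, ...) {
  cat(sprintf("label_score_matrix: %d cells x %d labels (%d flagged ambiguous)\n",
              nrow(x$scores), ncol(x$scores), sum(x$ambiguous)))
  invisible(x)
}

#' Flag cells with two nearly equal top labels
#'
#' A cell is ambiguous when the gap between its two highest scores falls in
#' the bottom `quantile` of gaps across all cells (gap <= the empirical
#' quantile of gaps; R's default quantile definition). With identical gaps
#' everywhere all cells are flagged.
#'
#' @param scores a `label_score_matrix` with >= 2 labels.
#' @param quantile fraction in (0, 1); default 0.10.
#' @return logical per-cell vector.
#' @export
flag_ambiguous <- function(scores, quantile = 0.10) {
  if (ncol(scores$scores) < 2) stop("need >= 2 labels to assess ambiguity")
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
  thr <- stats::quantile(scores$gap, probs = quantile, names = FALSE)
  out <- scores$gap <= thr
  names(out) <- rownames(scores$scores)
  out
}

#' Hierarchically cluster labels by label-to-label influence
#'
#' Euclidean distances between the rows of the label-to-label block of F
#' (diagonal included) feed agglomerative clustering; complete linkage by
#' default, matching the default of R's standard routine.
#'
#' @param F an `influence_matrix` with >= 2 labels.
#' @param method linkage passed to [stats::hclust()].
#' @return an `hclust` object over labels (serializable to Newick with
#'   [write_dendrogram()]).
#' @export
cluster_labels <- function(F, method = "complete") {
  ltl <- label_to_label(F)
  if (nrow(ltl) < 2) stop("need >= 2 labels to cluster")
  hclust(dist(ltl, method = "euclidean"), method = method)
}

#' Map bulk genomic regions to labels
#'
#' Distributes bulk signal (e.g. candidate enhancers) to cell-type labels
#' through cell-to-label influence. Two modes:
#' \describe{
#'   \item{binary_peak}{score(region, label) = sum over cells that have at
#'     least one accessible peak overlapping the region of
#'     `cell_to_label[label, cell]`.}
#'   \item{read_fraction}{each cell contributes its influence weighted by
#'     (reads of the cell in peaks overlapping the region) / (total reads
#'     of the cell).}
#' }
#' Regions with no overlapping accessible peak get an all-zero row.
#'
#' @param F an `influence_matrix`.
#' @param matrix the peak/bin `cell_matrix` the graph was built from.
#' @param regions a `genomic_intervals` set of bulk regions.
#' @param mode `"binary_peak"` or `"read_fraction"`.
#' @return a `region_label_scores`: list(scores [regions x labels],
#'   regions, mode). Region rownames are `chrom:start-end`.
#' @export
map_regions_to_labels <- function(F, matrix, regions,
                                  mode = c("binary_peak", "read_fraction")) {
  mode <- match.arg(mode)
  if (!inherits(matrix, "cell_matrix") || matrix$feature_kind == "gene")
    stop("matrix must be a peak/bin cell_matrix")
  ctl <- cell_to_label(F)                       # m x n
  hits <- GenomicRanges::findOverlaps(gis_to_granges(matrix$features),
                                      gis_to_granges(regions),
                                      ignore.strand = TRUE)
  # p x R indicator of peak-in-region
  ind <- Matrix::sparseMatrix(i = S4Vectors::queryHits(hits),
                              j = S4Vectors::subjectHits(hits), x = 1,
                              dims = c(ncol(matrix$values), nrow(regions)))
  if (mode == "binary_peak") {
    b <- .as_dgc(matrix$values > 0)
    cellin <- as.matrix(b %*% ind) > 0          # n x R: cell has peak in region
    sc <- t(cellin) %*% t(ctl)                  # R x m
  } else {
    reads_in <- as.matrix(matrix$values %*% ind)  # n x R reads in region
    tot <- Matrix::rowSums(matrix$values)
    frac <- reads_in / ifelse(tot > 0, tot, 1)
    sc <- t(frac) %*% t(ctl)
  }
  sc <- as.matrix(sc)
  rownames(sc) <- sprintf("%s:%d-%d", regions$chrom, regions$start,
                          regions$end)
  colnames(sc) <- F$labels
  structure(list(scores = sc, regions = regions, mode = mode),
            class = "region_label_scores")
}

#' Per-cell difference between two label scores
#'
#' A progression-style score: score(label_late) - score(label_early), so
#' that higher values mean "later". Optionally restricted to cells whose
#' top label is one of the two.
#'
#' @param scores a `label_score_matrix`.
#' @param label_late,label_early label names present in the score matrix.
#' @param restrict_top if TRUE, keep only cells whose top label is
#'   `label_late` or `label_early`.
#' @return named numeric vector (possibly shorter than n when restricted).
#' @export
score_difference <- function(scores, label_late, label_early,
                             restrict_top = FALSE) {
  sc <- scores$scores
  for (l in c(label_late, label_early))
    if (!l %in% colnames(sc)) stop("unknown label: ", l)
  out <- sc[, label_late] - sc[, label_early]
  names(out) <- rownames(sc)
  if (restrict_top)
    out <- out[scores$top_label %in% c(label_late, label_early)]
  out
}

# distal peaks: accessible peaks overlapping neither gene bodies nor
# promoter windows
.distal_peak_mask <- function(features, annotation, upstream_bp = 2000) {
  windows <- promoter_windows(annotation, upstream_bp)
  hits <- GenomicRanges::findOverlaps(gis_to_granges(features),
                                      gis_to_granges(windows),
                                      ignore.strand = TRUE)
  mask <- rep(TRUE, nrow(features))
  mask[unique(S4Vectors::queryHits(hits))] <- FALSE
  mask
}

#' Correlate per-region distal accessibility with a per-cell score
#'
#' Distal peaks are those overlapping neither a gene body nor a promoter
#' window. For region r and cell c, x_c = (c's accessible distal peaks in
#' r) / (c's accessible distal peaks genome-wide); the output is the
#' per-region Pearson correlation of x with the per-cell score. Regions
#' whose x has zero variance get NA.
#'
#' @param matrix peak `cell_matrix`.
#' @param regions `genomic_intervals` (e.g. TADs).
#' @param per_cell_score named numeric vector over the analyzed cells
#'   (names must be cell ids of `matrix`).
#' @param annotation `gene_annotation` used to exclude non-distal peaks.
#' @param upstream_bp promoter window size.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return named numeric vector of per-region correlations (NA where
#'   undefined).
#' @export
correlate_regions_with_score <- function(matrix, regions, per_cell_score,
                                         annotation, upstream_bp = 2000,
                                         method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (nrow(regions) == 0) stop("empty region set")
  cells <- names(per_cell_score)
  if (is.null(cells) || !all(cells %in% matrix$cell_ids))
    stop("per_cell_score must be named by cell ids present in the matrix")
  if (length(cells) < 3) stop("need >= 3 cells to correlate")
  distal <- .distal_peak_mask(matrix$features, annotation, upstream_bp)
  b <- .as_dgc(matrix$values > 0)
  b <- b[match(cells, matrix$cell_ids), distal, drop = FALSE]
  feats <- matrix$features[distal, , drop = FALSE]
  hits <- GenomicRanges::findOverlaps(gis_to_granges(feats),
                                      gis_to_granges(regions),
                                      ignore.strand = TRUE)
  ind <- Matrix::sparseMatrix(i = S4Vectors::queryHits(hits),
                              j = S4Vectors::subjectHits(hits), x = 1,
                              dims = c(ncol(b), nrow(regions)))
  in_region <- as.matrix(b %*% ind)             # cells x regions
  tot <- Matrix::rowSums(b)
  x <- in_region / ifelse(tot > 0, tot, 1)
  out <- suppressWarnings(
    apply(x, 2, function(col) {
      if (sd(col) == 0 || sd(per_cell_score) == 0) NA_real_
      else cor(col, per_cell_score, method = method)
    }))
  names(out) <- sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end)
  out
}

# relocate regions uniformly within their chromosome, preserving lengths
# and pairwise non-overlap; simple rejection sampling per region
.permute_regions <- function(regions, chrom_sizes, excluded = NULL,
                             max_tries = 200) {
  new_start <- numeric(nrow(regions))
  placed <- vector("list", length(chrom_sizes))
  names(placed) <- names(chrom_sizes)
  excl <- if (!is.null(excluded)) split(excluded, excluded$chrom) else NULL
  for (i in seq_len(nrow(regions))) {
    chrom <- regions$chrom[i]
    len <- regions$end[i] - regions$start[i]
    size <- chrom_sizes[[chrom]]
    if (is.null(size) || len > size)
      stop("region longer than its chromosome: ", chrom)
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      s <- floor(runif(1, 0, size - len + 1))
      clash <- FALSE
      prev <- placed[[chrom]]
      if (!is.null(prev) && nrow(prev))
        clash <- any(s < prev$end & prev$start < s + len)
      if (!clash && !is.null(excl[[chrom]]) && nrow(excl[[chrom]])) {
        e <- excl[[chrom]]
        clash <- any(s < e$end & e$start < s + len)
      }
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place permuted region without overlap on ", chrom)
    new_start[i] <- s
    placed[[chrom]] <- rbind(placed[[chrom]],
                             data.frame(start = s, end = s + len))
  }
  genomic_intervals(regions$chrom, new_start,
                    new_start + (regions$end - regions$start))
}

#' Permutation test for bimodality of region-score correlations
#'
#' Statistic: median |correlation| across regions. Null: regions relocated
#' uniformly at random within their chromosomes, preserving lengths and
#' pairwise non-overlap (optionally avoiding `excluded` intervals), with
#' correlations recomputed against the same per-cell score. The empirical
#' p-value uses the add-one correction,
#' p = (1 + #\{null >= observed\}) / (n_perm + 1).
#'
#' @param matrix,regions,per_cell_score,annotation,upstream_bp as in
#'   [correlate_regions_with_score()].
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @param excluded optional `genomic_intervals` that permuted regions must
#'   avoid.
#' @return list(p_value, observed, null_stats).
#' @export
bimodality_permutation_test <- function(matrix, regions, per_cell_score,
                                        annotation, chrom_sizes,
                                        n_perm = 1000, seed = 1,
                                        upstream_bp = 2000, excluded = NULL) {
  obs_cor <- correlate_regions_with_score(matrix, regions, per_cell_score,
                                          annotation, upstream_bp)
  observed <- median(abs(obs_cor), na.rm = TRUE)
  set.seed(seed)
  null_stats <- vapply(seq_len(n_perm), function(i) {
    perm <- .permute_regions(regions, chrom_sizes, excluded)
    r <- correlate_regions_with_score(matrix, perm, per_cell_score,
                                      annotation, upstream_bp)
    median(abs(r), na.rm = TRUE)
  }, numeric(1))
  p <- (1 + sum(null_stats >= observed)) / (n_perm + 1)
  list(p_value = p, observed = observed, null_stats = null_stats)
}

# nearest gene by TSS-to-region-midpoint distance; ties -> smaller TSS
# coordinate, then annotation order
.nearest_genes <- function(regions, annotation) {
  mid <- (regions$start + regions$end) / 2
  out <- character(nrow(regions))
  ord <- order(annotation$tss)
  for (chrom in unique(regions$chrom)) {
    ann <- annotation[annotation$chrom == chrom, , drop = FALSE]
    if (nrow(ann) == 0)
      stop("no annotated genes on chromosome ", chrom)
    ann <- ann[order(ann$tss), , drop = FALSE]
    idx <- which(regions$chrom == chrom)
    for (i in idx) {
      d <- abs(ann$tss - mid[i])
      best <- which(d == min(d))[1]   # sorted by tss => smaller coordinate
      out[i] <- ann$gene[best]
    }
  }
  out
}

#' Nearest-gene resampling enrichment of region subsets in gene sets
#'
#' Each region is assigned its nearest gene (TSS to region midpoint;
#' deterministic tie-break toward the smaller coordinate). For each
#' (region subset, gene set) pair, the observed statistic is the fraction
#' of the subset's regions whose nearest gene is in the gene set; the null
#' redraws an equally sized gene set uniformly without replacement from the
#' background and recomputes the fraction. One-sided empirical p-values use
#' the add-one correction; FDRs are Benjamini-Hochberg across all pairs.
#'
#' @param regions_by_subset named list of `genomic_intervals` sets (e.g.
#'   regions specific to each cell type).
#' @param gene_sets named list of character vectors (e.g. disease genes).
#' @param background_genes character vector to resample from (e.g. all
#'   expressed genes). A warning is raised for gene sets disjoint from it.
#' @param annotation a `gene_annotation`.
#' @param n_resample resampling depth (default 10000).
#' @param seed RNG seed.
#' @return data.frame with columns subset, gene_set, observed_fraction,
#'   empirical_p, fdr.
#' @export
nearest_gene_enrichment <- function(regions_by_subset, gene_sets,
                                    background_genes, annotation,
                                    n_resample = 10000, seed = 1) {
  if (is.null(names(regions_by_subset)) || is.null(names(gene_sets)))
    stop("regions_by_subset and gene_sets must be named lists")
  background_genes <- unique(background_genes)
  set.seed(seed)
  nearest <- lapply(regions_by_subset, .nearest_genes, annotation = annotation)
  rows <- list()
  for (gs_name in names(gene_sets)) {
    gs <- unique(gene_sets[[gs_name]])
    if (length(gs) > length(background_genes))
      stop("gene set '", gs_name, "' larger than background")
    if (!any(gs %in% background_genes))
      warning("gene set '", gs_name, "' disjoint from background")
    k <- length(gs)
    for (sub_name in names(regions_by_subset)) {
      ng <- nearest[[sub_name]]
      observed <- mean(ng %in% gs)
      # count nearest-gene hits per background gene once; each resample is
      # then a sum over k sampled genes
      cnt <- table(factor(ng[ng %in% background_genes],
                          levels = background_genes))
      cnt <- as.numeric(cnt)
      nreg <- length(ng)
      res <- vapply(seq_len(n_resample), function(i) {
        sum(cnt[sample.int(length(background_genes), k)]) / nreg
      }, numeric(1))
      p <- (1 + sum(res >= observed)) / (n_resample + 1)
      rows[[length(rows) + 1]] <- data.frame(
        subset = sub_name, gene_set = gs_name,
        observed_fraction = observed, empirical_p = p)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$empirical_p, method = "BH")
  out
}
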