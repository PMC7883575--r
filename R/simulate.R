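# Synthetic scATAC-seq generator: two cell types over p genomic bins with
# a shared global read propensity, type-specific extra reads on each type's
# half of the bins, partial/incorrect weight-1 labeling, add/drop read
# noise, and an optional unlabeled mixture population. Everything is
# deterministic given a seed, so the whole pipeline is testable without
# external data.

#' Simulation configuration
#'
#' Defaults encode the stated simulation world: 400 cells per type, a
#' lognormal read-depth distribution with median 5500 reads per cell,
#' 2000 bins with a symmetric Dirichlet(0.5) global propensity fixed by the
#' seed, medium type distinctness (5% extra type-specific reads), and 15%
#' of cells correctly labeled.
#'
#' @param n_per_type cells per type (default 400).
#' @param n_bins number of genomic bins p (default 2000).
#' @param distinctness_pct percent of extra reads placed on a cell's
#'   type-specific bins; 1/5/10 = low/medium/high.
#' @param frac_labeled fraction of cells given a correct weight-1 label
#'   edge (exact count, sampled without replacement).
#' @param frac_mislabeled fraction of cells given a wrong-label edge,
#'   drawn independently of the correctly labeled set.
#' @param noise_pct percent of each cell's reads added or dropped.
#' @param noise_mode `"add"` or `"drop"`.
#' @param depth_meanlog,depth_sdlog lognormal read-depth parameters;
#'   `exp(depth_meanlog)` is the median depth.
#' @param depth_empirical optional numeric vector of observed per-cell
#'   depths to resample from instead of the lognormal.
#' @param bin_propensity optional probability vector over bins; default is
#'   one Dirichlet(0.5) draw fixed by the simulation seed.
#' @param shuffle_bins if TRUE the type-specific bin partition is a random
#'   half/half split instead of first-half/second-half.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_per_type = 400, n_bins = 2000,
                              distinctness_pct = 5, frac_labeled = 0.15,
                              frac_mislabeled = 0, noise_pct = 0,
                              noise_mode = c("add", "drop"),
                              depth_meanlog = log(5500), depth_sdlog = 0.5,
                              depth_empirical = NULL, bin_propensity = NULL,
                              shuffle_bins = FALSE) {
  noise_mode <- match.arg(noise_mode)
  stopifnot(n_per_type >= 1, n_bins >= 2, distinctness_pct >= 0,
            frac_labeled >= 0, frac_labeled <= 1,
            frac_mislabeled >= 0, frac_mislabeled <= 1, noise_pct >= 0)
  if (!is.null(bin_propensity)) {
    if (length(bin_propensity) != n_bins || any(bin_propensity < 0))
      stop("bin_propensity must be a nonnegative vector of length n_bins")
    bin_propensity <- bin_propensity / sum(bin_propensity)
  }
  structure(list(n_per_type = n_per_type, n_bins = n_bins,
                 distinctness_pct = distinctness_pct,
                 frac_labeled = frac_labeled,
                 frac_mislabeled = frac_mislabeled,
                 noise_pct = noise_pct, noise_mode = noise_mode,
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 depth_empirical = depth_empirical,
                 bin_propensity = bin_propensity,
                 shuffle_bins = shuffle_bins),
            class = "simulation_config")
}

.draw_depths <- function(config, n) {
  emp <- config$depth_empirical
  if (!is.null(emp)) {
    if (length(emp) == 1) rep(emp, n) else sample(emp, n, replace = TRUE)
  } else {
    pmax(1, round(rlnorm(n, config$depth_meanlog, config$depth_sdlog)))
  }
}

# multinomial counts for one cell over a propensity vector
.spread_reads <- function(total, prob) {
  if (total <= 0) return(integer(length(prob)))
  as.integer(rmultinom(1, total, prob))
}

# bins as BED intervals on a pseudo-chromosome, 1 kb each
.bin_intervals <- function(p, width = 1000) {
  genomic_intervals(rep("chrSim", p), (seq_len(p) - 1) * width,
                    seq_len(p) * width,
                    name = paste0("bin", seq_len(p)))
}

#' Simulate two cell types of scATAC-seq-like bin counts
#'
#' Per cell: draw a total read depth, spread it multinomially over the bins
#' by the global propensity, then add `distinctness_pct`% extra reads
#' multinomially and uniformly over the cell's type's half of the bins,
#' so type-specific reads can open bins the shared propensity leaves
#' closed. Bins are split half/half by index (first half = type1) unless
#' `shuffle_bins`. Label edges are built per the config's
#' labeled/mislabeled fractions.
#'
#' @param config a `simulation_config`.
#' @param seed integer seed; the dataset is bit-identical for equal
#'   (config, seed).
#' @return a `simulated_dataset`: list(matrix [`cell_matrix`, bins],
#'   true_type, label_edges [2 x n, 0/1], propensity, type_bins,
#'   config, seed).
#' @export
simulate_two_types <- function(config = simulation_config(), seed = 1) {
  if (config$n_bins < 2) stop("need at least 2 bins")
  set.seed(seed)
  p <- config$n_bins
  n <- 2 * config$n_per_type
  prop <- config$bin_propensity
  if (is.null(prop)) {
    g <- rgamma(p, shape = 0.5)
    g[g == 0] <- .Machine$double.xmin
    prop <- g / sum(g)
  }
  bin_order <- if (config$shuffle_bins) sample.int(p) else seq_len(p)
  half <- floor(p / 2)
  type_bins <- list(type1 = sort(bin_order[seq_len(half)]),
                    type2 = sort(bin_order[(half + 1):p]))
  depths <- .draw_depths(config, n)
  true_type <- rep(c("type1", "type2"), each = config$n_per_type)
  counts <- base::matrix(0L, nrow = n, ncol = p)
  for (i in seq_len(n)) {
    base_reads <- .spread_reads(depths[i], prop)
    tb <- type_bins[[true_type[i]]]
    extra_n <- round(config$distinctness_pct / 100 * depths[i])
    extra <- integer(p)
    if (extra_n > 0) {
      # uniform over the type's bins: extras must be able to open bins the
      # base propensity leaves closed, or binarized profiles never separate
      extra[tb] <- .spread_reads(extra_n, rep(1 / length(tb), length(tb)))
    }
    counts[i, ] <- base_reads + extra
  }
  cm <- cell_matrix(counts, paste0("cell", seq_len(n)), .bin_intervals(p),
                    feature_kind = "bin")
  le <- make_label_edges(true_type, config$frac_labeled,
                         config$frac_mislabeled,
                         seed = seed + 7919L)
  if (config$noise_pct > 0)
    cm <- perturb_reads(cm, config$noise_pct, config$noise_mode,
                        seed = seed + 104729L, bin_propensity = prop)
  structure(list(matrix = cm, true_type = true_type, label_edges = le,
                 propensity = prop, type_bins = type_bins,
                 config = config, seed = seed),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("simulated_dataset: %d cells x %d bins (%s)\n",
              nrow(x$matrix$values), ncol(x$matrix$values),
              paste(names(table(x$true_type)), table(x$true_type),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Partial / incorrect weight-1 label edges
#'
#' An exact `round(frac_labeled * n)` cells, sampled without replacement,
#' get a weight-1 edge to their true type's label; an independently drawn
#' `round(frac_mislabeled * n)` cells get a weight-1 edge to a wrong label.
#' The two sets may overlap (a cell can carry both a correct and a wrong
#' edge). Unlabeled cells have all-zero columns.
#'
#' @param true_type per-cell type id.
#' @param frac_labeled,frac_mislabeled fractions in `[0, 1]`.
#' @param seed integer seed.
#' @param labels label universe; defaults to the sorted unique types
#'   (mixture cells, whose type is not a label, never receive edges).
#' @return labels x cells 0/1 matrix.
#' @export
make_label_edges <- function(true_type, frac_labeled, frac_mislabeled = 0,
                             seed = 1, labels = NULL) {
  stopifnot(frac_labeled >= 0, frac_labeled <= 1,
            frac_mislabeled >= 0, frac_mislabeled <= 1)
  set.seed(seed)
  if (is.null(labels))
    labels <- sort(unique(true_type[!grepl("^mixture", true_type)]))
  n <- length(true_type)
  w <- matrix(0, nrow = length(labels), ncol = n,
              dimnames = list(labels, names(true_type)))
  eligible <- which(true_type %in% labels)
  n_lab <- round(frac_labeled * n)
  n_mis <- round(frac_mislabeled * n)
  if (n_lab > 0) {
    chosen <- sample(eligible, min(n_lab, length(eligible)))
    w[cbind(match(true_type[chosen], labels), chosen)] <- 1
  }
  if (n_mis > 0 && length(labels) >= 2) {
    chosen <- sample(eligible, min(n_mis, length(eligible)))
    for (c in chosen) {
      wrong <- setdiff(seq_along(labels), match(true_type[c], labels))
      pick <- if (length(wrong) == 1) wrong else sample(wrong, 1)
      w[pick, c] <- 1
    }
  }
  w
}

#' Add or drop a fixed percentage of each cell's reads
#'
#' Drop mode removes `floor(noise_pct% * total)` reads uniformly at random
#' from the multiset of the cell's reads; add mode adds the same count
#' multinomially according to the global bin propensity.
#'
#' @param matrix a bin/peak `cell_matrix`.
#' @param noise_pct percentage in `[0, 100]` for drop; >= 0 for add.
#' @param mode `"add"` or `"drop"`.
#' @param seed integer seed.
#' @param bin_propensity propensity used for added reads; defaults to the
#'   empirical pooled bin distribution of the matrix.
#' @return a perturbed `cell_matrix`.
#' @export
perturb_reads <- function(matrix, noise_pct, mode = c("add", "drop"),
                          seed = 1, bin_propensity = NULL) {
  mode <- match.arg(mode)
  if (noise_pct < 0) stop("noise_pct must be >= 0")
  if (mode == "drop" && noise_pct > 100) stop("cannot drop more than 100%")
  if (noise_pct == 0) return(matrix)
  set.seed(seed)
  counts <- as.matrix(matrix$values)
  p <- ncol(counts)
  if (is.null(bin_propensity)) {
    cs <- colSums(counts)
    bin_propensity <- if (sum(cs) > 0) cs / sum(cs) else rep(1 / p, p)
  }
  for (i in seq_len(nrow(counts))) {
    total <- sum(counts[i, ])
    k <- floor(noise_pct / 100 * total)
    if (k == 0) next
    if (mode == "drop") {
      reads <- rep.int(seq_len(p), counts[i, ])
      gone <- sample.int(length(reads), k)
      removed <- tabulate(reads[gone], nbins = p)
      counts[i, ] <- counts[i, ] - removed
    } else {
      counts[i, ] <- counts[i, ] + .spread_reads(k, bin_propensity)
    }
  }
  cell_matrix(counts, matrix$cell_ids, matrix$features, matrix$feature_kind)
}

#' Append an unlabeled mixture population
#'
#' Generates `n_cells` new cells whose bin propensity blends the global
#' vector with the propensity restricted to one base type's bins:
#' `(1 - mix_proportion) * global + mix_proportion * restricted(type)`.
#' The new cells carry no label edges and `true_type`
#' `"mixture(<type>,<proportion>)"`.
#'
#' @param base a two-type `simulated_dataset`.
#' @param mix_proportion blending weight in (0, 1); the stated range of
#'   interest is 0.1-0.5.
#' @param n_cells number of mixture cells (0 returns `base` unchanged).
#' @param toward which base type the mixture leans to (`"type1"` or
#'   `"type2"`).
#' @param seed integer seed.
#' @return a `simulated_dataset` with the mixture cells appended.
#' @export
simulate_mixture_population <- function(base, mix_proportion = 0.5,
                                        n_cells = 400, toward = "type1",
                                        seed = 1) {
  if (!inherits(base, "simulated_dataset")) stop("base must be a simulated_dataset")
  if (!setequal(unique(base$true_type), c("type1", "type2")))
    stop("base must contain exactly the two original types")
  if (mix_proportion <= 0 || mix_proportion >= 1)
    stop("mix_proportion must lie in (0, 1)")
  if (!toward %in% c("type1", "type2")) stop("toward must be type1 or type2")
  if (n_cells == 0) return(base)
  set.seed(seed)
  p <- base$config$n_bins
  prop <- base$propensity
  tb <- base$type_bins[[toward]]
  enriched <- numeric(p)
  enriched[tb] <- 1 / length(tb)   # same uniform enrichment the base types get
  blend <- (1 - mix_proportion) * prop + mix_proportion * enriched
  depths <- .draw_depths(base$config, n_cells)
  counts <- base::matrix(0L, nrow = n_cells, ncol = p)
  for (i in seq_len(n_cells))
    counts[i, ] <- .spread_reads(depths[i], blend)
  n0 <- nrow(base$matrix$values)
  all_counts <- rbind(as.matrix(base$matrix$values), counts)
  ids <- c(base$matrix$cell_ids, paste0("mixcell", seq_len(n_cells)))
  cm <- cell_matrix(all_counts, ids, base$matrix$features, "bin")
  mix_id <- sprintf("mixture(%s,%g)", toward, mix_proportion)
  le <- cbind(base$label_edges,
              matrix(0, nrow(base$label_edges), n_cells))
  colnames(le) <- NULL
  structure(list(matrix = cm,
                 true_type = c(base$true_type, rep(mix_id, n_cells)),
                 label_edges = le, propensity = prop,
                 type_bins = base$type_bins, config = base$config,
                 seed = seed),
            class = "simulated_dataset")
}

#' Write a simulated dataset as MTX triplet plus truth tables
#'
#' Emits `<prefix>.mtx/.barcodes.tsv/.features.bed`, a truth TSV
#' (`cell_id`, `true_type`) and a label-edge TSV (label x cell 0/1 matrix).
#'
#' @param dataset a `simulated_dataset`.
#' @param prefix output path prefix.
#' @export
write_simulated_dataset <- function(dataset, prefix) {
  write_cell_matrix(dataset$matrix, prefix)
  truth <- data.frame(cell_id = dataset$matrix$cell_ids,
                      true_type = dataset$true_type)
  write.table(truth, paste0(prefix, ".truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  le <- data.frame(label = rownames(dataset$label_edges),
                   dataset$label_edges, check.names = FALSE)
  colnames(le) <- c("label", dataset$matrix$cell_ids)
  write.table(le, paste0(prefix, ".label_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
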