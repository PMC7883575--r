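# Small programmatic fixtures shared across test files. Everything is
# built in code; nothing is read from disk except what a test writes to
# tempfiles itself.

# tiny 2x3 peak matrix triplet written to tempfiles; returns the paths
write_tiny_triplet <- function(dir = tempfile("triplet"),
                               transpose_on_disk = FALSE) {
  dir.create(dir)
  m <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 3), x = c(2, 1),
                            dims = c(2, 3))
  if (transpose_on_disk) m <- Matrix::t(m)
  mtx <- file.path(dir, "m.mtx")
  Matrix::writeMM(m, mtx)
  bar <- file.path(dir, "barcodes.tsv")
  writeLines(c("cellA", "cellB"), bar)
  bed <- file.path(dir, "peaks.bed")
  writeLines(c("chr1\t0\t100", "chr1\t200\t300", "chr2\t0\t50"), bed)
  list(mtx = mtx, barcodes = bar, features = bed)
}

# an influence_matrix with prescribed blocks (row-stochasticity not
# required for block-level unit tests)
fake_influence <- function(label_to_cell_block = NULL,
                           cell_to_cell_block = NULL,
                           label_to_label_block = NULL,
                           cell_ids = NULL, labels = NULL, alpha = 0.5) {
  n <- if (!is.null(label_to_cell_block)) nrow(label_to_cell_block)
       else nrow(cell_to_cell_block)
  m <- if (!is.null(label_to_cell_block)) ncol(label_to_cell_block)
       else if (!is.null(label_to_label_block)) nrow(label_to_label_block)
       else 2
  if (is.null(cell_ids)) cell_ids <- paste0("c", seq_len(n))
  if (is.null(labels)) labels <- paste0("L", seq_len(m))
  q <- n + m
  f <- matrix(0, q, q, dimnames = list(c(cell_ids, labels),
                                       c(cell_ids, labels)))
  # accessors transpose, so place blocks transposed
  if (!is.null(label_to_cell_block))
    f[n + seq_len(m), seq_len(n)] <- t(label_to_cell_block)
  if (!is.null(cell_to_cell_block))
    f[seq_len(n), seq_len(n)] <- t(cell_to_cell_block)
  if (!is.null(label_to_label_block))
    f[n + seq_len(m), n + seq_len(m)] <- t(label_to_label_block)
  structure(list(F = f, alpha = alpha, cell_ids = cell_ids, labels = labels),
            class = "influence_matrix")
}

# random row-stochastic walk matrix on a connected random graph
random_walk_matrix <- function(q, seed) {
  set.seed(seed)
  a <- matrix(runif(q * q), q)
  a <- a + t(a)
  diag(a) <- 0
  w <- a / rowSums(a)
  w
}

# tiny annotation: 4 genes on 2 chromosomes
tiny_annotation <- function() {
  gene_annotation(gene = c("G1", "G2", "G3", "G4"),
                  chrom = c("chr1", "chr1", "chr2", "chr2"),
                  start = c(1000, 9000, 500, 7000),
                  end = c(3000, 12000, 2500, 9000),
                  strand = c("+", "-", "+", "-"))
}

# memoised heavy simulation battery shared between acceptance sub-tests;
# computed once per test session
.sim_cache <- new.env(parent = emptyenv())

sim_battery <- function(n_seeds = 10) {
  key <- paste0("battery", n_seeds)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  grid <- 10^seq(-4, -1)
  out <- lapply(seq_len(n_seeds), function(seed) {
    cfg <- simulation_config()     # 400/type, p = 2000, medium distinctness
    ds <- simulate_two_types(cfg, seed = seed)
    J <- jaccard_cell_similarity(ds$matrix)
    tab <- tune_label_weight(J, ds$label_edges, grid = grid)
    best <- best_edge_weight(tab)
    # accuracy on unlabeled cells at best s, per mislabeling fraction
    acc_mis <- vapply(c(0, 0.075, 0.15), function(mis) {
      le <- make_label_edges(ds$true_type, 0.15, mis, seed = seed + 7919L)
      f <- run_diffusion(J, le, best)
      labeling_accuracy(assign_top_labels(f), ds$true_type,
                        colSums(le) == 0)
    }, numeric(1))
    # 50% read drop
    ds_drop <- simulate_two_types(
      simulation_config(noise_pct = 50, noise_mode = "drop"), seed = seed)
    f_drop <- run_diffusion(jaccard_cell_similarity(ds_drop$matrix),
                            ds_drop$label_edges, best)
    acc_drop <- labeling_accuracy(assign_top_labels(f_drop),
                                  ds_drop$true_type,
                                  colSums(ds_drop$label_edges) == 0)
    # unlabeled mixture population leaning to type1
    mix <- simulate_mixture_population(ds, mix_proportion = 0.5,
                                       n_cells = 400, toward = "type1",
                                       seed = seed + 13L)
    f_mix <- run_diffusion(jaccard_cell_similarity(mix$matrix),
                           mix$label_edges, best)
    a_mix <- assign_top_labels(f_mix)
    frac_mix_type1 <- mean(a_mix[grepl("^mixture", mix$true_type)] == "type1")
    list(tab = tab, best = best, acc_mis = acc_mis, acc_drop = acc_drop,
         frac_mix_type1 = frac_mix_type1)
  })
  .sim_cache[[key]] <- out
  out
}
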