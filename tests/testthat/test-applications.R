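test_that("label scores z-score columns then rescale rows to max one", {
  fi <- fake_influence(label_to_cell_block = rbind(c(0.4, 0.1),
                                                   c(0.2, 0.3)))
  sc <- label_scores(fi)
  expect_equal(unname(sc$scores), rbind(c(1, -1), c(-1, 1)),
               tolerance = 1e-12)
  expect_equal(unname(sc$top_label), c("L1", "L2"))
  expect_equal(sc$gap, c(2, 2))

  # zero-spread column maps to zeros, other column still informative
  fi2 <- fake_influence(label_to_cell_block = cbind(c(0.2, 0.2, 0.2),
                                                    c(0.1, 0.2, 0.3)))
  sc2 <- label_scores(fi2)
  expect_equal(unname(sc2$scores[, 1]), c(0, 0, 0))
  expect_equal(max(sc2$scores[3, ]), 1)

  # single label: every cell with positive z scores exactly 1
  fi3 <- fake_influence(label_to_cell_block = matrix(c(0.1, 0.4, 0.2), 3))
  expect_equal(unname(label_scores(fi3)$scores[2, 1]), 1)

  expect_error(label_scores(
    fake_influence(label_to_cell_block = matrix(0.5, 1, 2))), "single cell")
})

test_that("row maxima equal one whenever the top column has spread", {
  set.seed(21)
  fi <- fake_influence(label_to_cell_block = matrix(runif(30), 10, 3))
  sc <- label_scores(fi)
  expect_equal(apply(sc$scores, 1, max), rep(1, 10), ignore_attr = TRUE)
})

test_that("ambiguity flags the bottom quantile of score gaps", {
  gaps <- c(0.01, seq(0.2, 1, length.out = 9))
  sc <- structure(list(scores = matrix(0, 10, 2,
                                       dimnames = list(paste0("c", 1:10),
                                                       c("A", "B"))),
                       gap = gaps), class = "label_score_matrix")
  flags <- flag_ambiguous(sc, quantile = 0.10)
  expect_equal(sum(flags), 1)
  expect_true(flags[["c1"]])
  expect_equal(sum(flag_ambiguous(sc, quantile = 0.5)), 5)
  sc$gap <- rep(0.3, 10)
  expect_true(all(flag_ambiguous(sc, 0.10)))
  expect_error(flag_ambiguous(sc, 0), "quantile")
})

test_that("label clustering merges identical rows first and is
           order-insensitive", {
  ltl <- rbind(c(0.5, 0.2, 0.1), c(0.5, 0.2, 0.1), c(0.1, 0.1, 0.9))
  fi <- fake_influence(label_to_label_block = ltl,
                       cell_to_cell_block = diag(2),
                       labels = c("A", "B", "C"))
  hc <- cluster_labels(fi)
  expect_equal(hc$height[1], 0)                      # A, B identical
  expect_setequal(hc$labels[-hc$merge[1, ]], c("A", "B"))
  # two labels: single merge at the euclidean distance
  fi2 <- fake_influence(label_to_label_block = rbind(c(1, 0), c(0, 1)),
                        cell_to_cell_block = diag(2), labels = c("A", "B"))
  hc2 <- cluster_labels(fi2)
  expect_equal(hc2$height, sqrt(2))
  # permuting label order preserves the merge heights
  perm_block <- ltl[c(3, 1, 2), c(3, 1, 2)]
  fi3 <- fake_influence(label_to_label_block = perm_block,
                        cell_to_cell_block = diag(2),
                        labels = c("C", "A", "B"))
  expect_equal(sort(cluster_labels(fi3)$height), sort(hc$height))
})

test_that("bulk regions map to labels through overlapping accessible peaks", {
  feats <- genomic_intervals(rep("chr1", 3), c(0, 1000, 5000),
                             c(200, 1200, 5200))
  counts <- rbind(c(2, 0, 8), c(0, 3, 0))     # c1 has peaks 1,3; c2 peak 2
  cm <- cell_matrix(counts, c("c1", "c2"), feats, "peak")
  ctl <- rbind(c(0.6, 0.3), c(0.4, 0.7))      # labels x cells influence
  fi <- fake_influence(label_to_cell_block = t(ctl),
                       cell_ids = c("c1", "c2"), labels = c("A", "B"))
  # make cell_to_label return ctl: influence of cell c on label l
  fi$F[1:2, 3:4] <- t(ctl)
  regions <- genomic_intervals(c("chr1", "chr1"), c(100, 9000),
                               c(1100, 9500))
  rl <- map_regions_to_labels(fi, cm, regions, mode = "binary_peak")
  # region 1 overlaps peak1 (c1 accessible) and peak2 (c2 accessible)
  expect_equal(unname(rl$scores[1, ]), c(0.6 + 0.3, 0.4 + 0.7))
  expect_equal(unname(rl$scores[2, ]), c(0, 0))     # no overlap
  expect_equal(rownames(rl$scores), c("chr1:100-1100", "chr1:9000-9500"))

  rf <- map_regions_to_labels(fi, cm, regions, mode = "read_fraction")
  # c1: 2 of 10 reads in region 1; c2: 3 of 3 reads
  expect_equal(unname(rf$scores[1, ]), c(0.2 * 0.6 + 1 * 0.3,
                                         0.2 * 0.4 + 1 * 0.7))
  expect_error(map_regions_to_labels(fi, cm, regions, mode = "bogus"))
})

test_that("region scores are preserved row-wise under concatenation", {
  set.seed(3)
  feats <- genomic_intervals(rep("chr1", 10), (0:9) * 1000,
                             (0:9) * 1000 + 500)
  cm <- cell_matrix(matrix(rpois(40, 1), 4, 10), paste0("c", 1:4),
                    feats, "peak")
  fi <- fake_influence(label_to_cell_block = matrix(runif(8), 4, 2),
                       cell_ids = paste0("c", 1:4))
  fi$F[1:4, 5:6] <- matrix(runif(8), 4, 2)
  r1 <- genomic_intervals("chr1", 0, 1500)
  r2 <- genomic_intervals("chr1", 5000, 8000)
  both <- genomic_intervals(c("chr1", "chr1"), c(0, 5000), c(1500, 8000))
  s1 <- map_regions_to_labels(fi, cm, r1, "binary_peak")$scores
  s2 <- map_regions_to_labels(fi, cm, r2, "binary_peak")$scores
  sb <- map_regions_to_labels(fi, cm, both, "binary_peak")$scores
  expect_identical(unname(sb), unname(rbind(s1, s2)))
})

test_that("score differences follow the higher-is-later convention", {
  fi <- fake_influence(label_to_cell_block = rbind(c(1.0, 0.2),
                                                   c(0.5, 0.5),
                                                   c(0.1, 0.9)),
                       labels = c("early", "late"))
  sc <- label_scores(fi)
  d <- score_difference(sc, label_late = "late", label_early = "early")
  expect_equal(length(d), 3)
  expect_lt(d[[1]], 0)      # early-dominant cell scores negative
  expect_gt(d[[3]], 0)
  expect_error(score_difference(sc, "late", "nope"), "unknown label")
  # restriction drops cells whose top label is neither
  fi2 <- fake_influence(label_to_cell_block = rbind(c(1, 0.2, 0.1),
                                                    c(0.1, 0.2, 1)),
                        labels = c("early", "late", "other"))
  sc2 <- label_scores(fi2)
  d2 <- score_difference(sc2, "late", "early", restrict_top = TRUE)
  expect_equal(length(d2), 1)
})

test_that("distal accessibility correlations behave like correlations", {
  ann <- gene_annotation("G1", "chr1", 100000, 110000, "+")
  p <- 20
  feats <- genomic_intervals(rep("chr1", p), (0:(p - 1)) * 1000,
                             (0:(p - 1)) * 1000 + 500)   # all distal
  score <- setNames(seq_len(6), paste0("c", 1:6))
  counts <- matrix(0, 6, p)
  # cells with higher score have more accessible peaks inside region 1
  for (i in 1:6) {
    counts[i, 1:i] <- 1          # peaks 1..i (region r1 covers peaks 1-10)
    counts[i, 11:20] <- 1        # constant background outside r1
  }
  cm <- cell_matrix(counts, names(score), feats, "peak")
  r1 <- genomic_intervals("chr1", 0, 10000)
  cors <- correlate_regions_with_score(cm, r1, score, ann)
  expect_gt(cors[[1]], 0.95)
  # sign antisymmetry
  cors_neg <- correlate_regions_with_score(cm, r1, -score, ann)
  expect_equal(unname(cors_neg), -unname(cors))
  # no overlapping peaks anywhere: zero variance -> NA
  r_const <- genomic_intervals("chr1", 50000, 60000)
  expect_true(is.na(correlate_regions_with_score(cm, r_const, score, ann)))
  expect_error(correlate_regions_with_score(cm, r1, score[1:2], ann),
               ">= 3 cells")
})

test_that("promoter/gene-body peaks are excluded from distal counts", {
  ann <- gene_annotation("G1", "chr1", 2500, 4000, "+")
  feats <- genomic_intervals(rep("chr1", 3), c(0, 3000, 8000),
                             c(100, 3100, 8100))
  mask <- walktype:::.distal_peak_mask(feats, ann, upstream_bp = 2000)
  # promoter window is [500, 2500): peak1 (0-100) stays distal, peak2 is
  # in the gene body, peak3 is distal
  expect_equal(mask, c(TRUE, FALSE, TRUE))
  mask4k <- walktype:::.distal_peak_mask(feats, ann, upstream_bp = 4000)
  expect_equal(mask4k, c(FALSE, FALSE, TRUE))  # wider promoter reaches peak1
})

test_that("bimodality permutation test separates signal from null", {
  set.seed(77)
  n_cells <- 12; p <- 120
  score <- setNames(scale(seq_len(n_cells))[, 1], paste0("c", 1:n_cells))
  feats <- genomic_intervals(rep("chr1", p), (0:(p - 1)) * 1000,
                             (0:(p - 1)) * 1000 + 200)
  # a gene far beyond all peaks: nothing is excluded as non-distal
  ann <- gene_annotation("G1", "chr1", 400000, 401000, "+")
  counts <- matrix(rbinom(n_cells * p, 1, 0.4), n_cells, p)
  # 8 signal regions of 5 peaks each whose accessibility tracks the score
  sig_start <- seq(0, by = 15000, length.out = 8)
  for (k in seq_along(sig_start)) {
    cols <- (sig_start[k] / 1000) + 1:5
    prob <- if (k %% 2 == 0) (rank(score) / n_cells) else rev(rank(score) / n_cells)
    counts[, cols] <- rbinom(n_cells * 5, 1, rep(prob * 0.9 + 0.05, 5))
  }
  cm <- cell_matrix(counts, names(score), feats, "peak")
  regions <- genomic_intervals(rep("chr1", 8), sig_start, sig_start + 5000)
  chrom_sizes <- c(chr1 = p * 1000)
  res <- bimodality_permutation_test(cm, regions, score, ann, chrom_sizes,
                                     n_perm = 99, seed = 5)
  expect_lte(res$p_value, 0.05)
  # null regions: random accessibility everywhere
  counts0 <- matrix(rbinom(n_cells * p, 1, 0.4), n_cells, p)
  cm0 <- cell_matrix(counts0, names(score), feats, "peak")
  res0 <- bimodality_permutation_test(cm0, regions, score, ann, chrom_sizes,
                                      n_perm = 99, seed = 5)
  expect_gt(res0$p_value, 0.1)
  # add-one correction bounds
  expect_equal(bimodality_permutation_test(cm, regions, score, ann,
                                           chrom_sizes, n_perm = 0,
                                           seed = 1)$p_value, 1)
  too_long <- genomic_intervals("chr1", 0, p * 1000 + 5)
  expect_error(suppressWarnings(
    bimodality_permutation_test(cm, too_long, score, ann, chrom_sizes,
                                n_perm = 1, seed = 1)))
})

test_that("nearest-gene enrichment: saturation, construction, BH wiring", {
  ann <- gene_annotation(paste0("G", 1:20), rep("chr1", 20),
                         (0:19) * 10000, (0:19) * 10000 + 500,
                         rep("+", 20))
  bg <- paste0("G", 1:20)
  near_g1 <- genomic_intervals(rep("chr1", 6), rep(0, 6) + (0:5) * 10,
                               rep(200, 6) + (0:5) * 10)  # all nearest G1
  # gene_set == background: every resample reproduces the observed fraction
  res <- nearest_gene_enrichment(list(sub = near_g1), list(all = bg), bg,
                                 ann, n_resample = 50, seed = 1)
  expect_equal(res$empirical_p, 1)
  expect_equal(res$observed_fraction, 1)
  # all regions nearest one gene, small target set: small p
  res2 <- nearest_gene_enrichment(list(sub = near_g1), list(hit = "G1"), bg,
                                  ann, n_resample = 400, seed = 2)
  expect_equal(res2$observed_fraction, 1)
  expect_lt(res2$empirical_p, 0.1)   # ~1/20 of resamples contain G1
  expect_error(nearest_gene_enrichment(list(s = near_g1),
                                       list(big = c(bg, "X")), bg, ann,
                                       n_resample = 10, seed = 1),
               "larger than background")
  # FDR column is Benjamini-Hochberg over all (subset, set) pairs
  sets <- list(hit = "G1", half = paste0("G", 1:10), all = bg)
  res3 <- nearest_gene_enrichment(list(sub = near_g1), sets, bg, ann,
                                  n_resample = 200, seed = 3)
  m <- nrow(res3)
  ord <- order(res3$empirical_p)
  bh <- res3$empirical_p * m / rank(res3$empirical_p, ties.method = "min")
  bh <- rev(cummin(rev(bh[ord])))[order(ord)]
  expect_equal(res3$fdr, pmin(1, bh))
})

test_that("nearest gene ties break toward the smaller TSS coordinate", {
  ann <- gene_annotation(c("B", "A"), c("chr1", "chr1"), c(0, 2000),
                         c(500, 2500), c("+", "+"))
  region <- genomic_intervals("chr1", 900, 1100)   # midpoint 1000: equidistant
  expect_equal(walktype:::.nearest_genes(region, ann), "B")
})
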