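# walktype

Cell-type annotation for single-cell ATAC-seq by graph diffusion.

scATAC-seq resolves chromatin accessibility in single cells, but each cell
is observed so sparsely that assigning it a cell type is unreliable on its
own. External information — marker genes for known cell types, typically
derived from scRNA-seq — is informative but connects only weakly and
unevenly to individual cells. `walktype` combines the two sources in one
network: cells are linked to each other by the similarity of their
accessibility profiles, and cell-type *label nodes* are linked to cells by
how strongly each cell's accessibility supports that type's marker genes.
Information is then propagated across the whole network with a random walk
with restarts, so that even a cell with no direct label evidence is
informed through its neighbors.

## The model

Let `A` be the symmetric adjacency over `q = n_cells + n_labels` nodes,
with cell–cell weights the Jaccard similarity of binarized accessibility,
label–cell weights derived from marker genes (peak fractions in gene
body + 2 kb promoter, or normalized gene activity scores, optionally
scaled by marker logFC), and no label–label edges. A single parameter `s`
sets the ratio of total label-edge weight to total cell-edge weight. With
walk matrix `W = D⁻¹A` and restart probability `α` (default 0.5), the
stationary information flow has the closed form

    F = α (I − (1 − α) W)⁻¹

The influence of node *j* on node *i* is the walk mass that starts at *j*
and ends at *i*. Blocks of this *influence matrix* drive four analyses:

* **label → cell**: fuzzy per-cell label scores (z-scored per label,
  rescaled to max 1), top-label assignment, and ambiguity calls
  (bottom 10% of top-two score gaps);
* **label → label**: hierarchical clustering of labels (Euclidean +
  complete linkage, exported as Newick);
* **cell → label**: mapping bulk genomic regions (e.g. candidate
  enhancers) to cell types;
* **cell → cell**: *cell homogeneity* — the natural log of the ratio of
  median within-type to median between-type influence — which is the
  objective used to tune `s` over a grid.

Annotation statistics built on top: label-score differences as a
progression score, per-region correlation of distal accessibility with a
per-cell score, a region-permutation test for bimodality of those
correlations, and nearest-gene resampling enrichment of region subsets in
gene sets with Benjamini–Hochberg FDR.

A full synthetic-data module generates scATAC-like two-type cell-by-bin
matrices (lognormal depths with median 5500, Dirichlet bin propensities,
type-specific extra reads, partial/incorrect labeling, add/drop read
noise, unlabeled mixture populations), so the entire pipeline is testable
with no external data.

## Worked example

```r
library(walktype)

cfg <- simulation_config(n_per_type = 100, n_bins = 1000,
                         distinctness_pct = 5, frac_labeled = 0.15)
ds  <- simulate_two_types(cfg, seed = 1)
J   <- jaccard_cell_similarity(ds$matrix)
tab <- tune_label_weight(J, ds$label_edges, grid = 10^seq(-4, 1))
tab
#>      s homogeneity n_ambiguous
#>  1e-04  0.02384905          20
#>  1e-03  0.02407941          20
#>  1e-02  0.02543403          20
#>  1e-01  0.02649286          20
#>  1e+00  0.02797190          20
#>  1e+01  0.02766540          20
best_edge_weight(tab)
#> [1] 1

f      <- run_diffusion(J, ds$label_edges, s = best_edge_weight(tab))
labels <- assign_top_labels(f)
mean(labels == ds$true_type)
#> [1] 0.98

sc <- label_scores(f)
sc$ambiguous <- flag_ambiguous(sc)
round(sc$scores[1:3, ], 3)
#>        type1  type2
#> cell1  1.000 -0.076
#> cell2 -0.322 -0.241
#> cell3 -0.322 -0.241
```

Homogeneity rises from ~0.024 toward its optimum at `s = 1` (where label
mass and cell mass balance) and declines past it; at the tuned weight 98%
of the 200 cells recover their true type, with only 15% of cells labeled
up front. In the score matrix each row is a cell: positive means
above-average influence from that label (rows with a positive maximum are
rescaled so their top label scores exactly 1); `cell1` is unambiguously
`type1`, while `cell2`'s two scores are close — cells like it are what the
ambiguity flag (bottom decile of top-two gaps) marks.

## Command line

`inst/cli/walktype.R` exposes subcommands `run`, `tune`, `label`,
`cluster-labels`, `map-bulk`, `simulate`, `enrich` over the same
functions, reading cellranger-style MTX triplets, BED interval files, and
marker TSVs. Example:

```sh
Rscript inst/cli/walktype.R simulate --config cfg.json --seed 3 --out-dir out
Rscript inst/cli/walktype.R tune --mtx out/sim.mtx --barcodes out/sim.barcodes.tsv \
    --features out/sim.features.bed --feature-kind bin \
    --markers markers.tsv --annotation genes.bed --grid 1e-2,1e2 --out-dir out
```

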