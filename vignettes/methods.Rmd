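---
title: "Diffusion-based cell typing: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion-based cell typing: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`walktype` treats cell typing in scATAC-seq as an information-propagation
problem on a heterogeneous network. Nodes are the `n` cells plus one node
per cell-type label. Edges come in two families:

* **cell–cell**: Jaccard similarity of binarized accessibility (an entry
  is "accessible" when its count exceeds 0). Jaccard of two empty
  supports, or of an empty support with anything, is defined as 0 — an
  uninformative cell should not attract walks. The diagonal is forced to
  0; self-information enters only through the restart.
* **label–cell**: marker-gene evidence. For cell-by-peak input, the
  fraction of a cell's accessible peaks falling in a marker's gene body
  or promoter (2 kb upstream of the TSS, strand-aware, clipped at 0),
  scaled by the marker's expression log-fold change when available (absent
  logFC counts as 1; non-positive logFC is rejected outright, because the
  walk requires nonnegative weights and a marker that is *down* in a type
  should not anchor that type). For cell-by-gene-score input, the
  logFC-weighted sum of the cell's gene scores after normalizing each
  cell's scores to sum to one.

There are no label–label edges: labels communicate only through cells.

With adjacency `A`, walk matrix `W = D⁻¹A` (zero-degree nodes receive a
unit self-loop so indexing stays aligned with the input cells), and
restart probability `α`, the walk with restarts converges and its
information flow has the closed form `F = α(I − (1 − α)W)⁻¹`, computed by
LU-factorized linear solves, never by power iteration. Each row of `F`
sums to 1 (asserted at 1e−8) and each diagonal entry is at least `α`.

### Orientation of influence

`F[i, j]` is the walk mass that *starts at i and ends at j*. We define the
influence of node `j` on node `i` as the mass starting at `j` that
arrives at `i`, i.e. `t(F)[i, j]`. The practical consequence concerns
cell labeling: label-to-cell influence is walk mass *leaving the label
node*, which the first walk step divides by the label's degree. Labels
anchored to many cells therefore do not dominate merely by being large.
We verified the alternative orientation (walks from the cell reaching the
label) empirically in simulations: because it lacks this normalization, a
modest sampling imbalance in how many cells of each type happen to be
labeled (binomial noise at 15% labeling is ~10%) overwhelms the diffusion
signal and collapses assignment onto the larger label. Under the chosen
orientation assignment is invariant to that imbalance. Both orientations
share the same `F`; only the block accessors differ by a transpose, so
every invariant on `W` and `F` (row sums, diagonal bound, the Neumann
series bound) is orientation-independent, as is cell homogeneity, which
pools ordered cell pairs.

### The label edge weight is a mass ratio

The single tuning parameter `s` is the ratio of total label-edge weight
to total cell-edge weight: `assemble()` multiplies the label block by
`s · sum(cell_edges) / sum(label_edges)`. Interpreting `s` as a raw
multiplier instead makes its meaning depend on the scale of the
similarity matrix — with hundreds of cells the cell degrees are O(100),
and every value of a raw multiplier below 1 lands in the same linear
regime where relative label influence is independent of `s`. As a ratio,
`s ≪ 1` reproduces de novo clustering (labels barely perturb the walk),
`s ≈ 1` balances the two information sources, and `s ≫ 1` approaches
direct label assignment, on any dataset. A `normalize_ratio = FALSE`
switch restores the raw-multiplier behavior.

## Tuning by cell homogeneity

Cell homogeneity is computed directly from the influence matrix: pool all
ordered off-diagonal cell–cell influences into within-group and
between-group sets and take the natural log of the ratio of the pooled
medians. Zero means within-type and between-type influence are
indistinguishable; the statistic is invariant to group relabeling, cell
permutation, and rescaling all influences. "Median ratio" admits another
reading (median of per-cell ratios); we use the ratio of pooled medians,
which stays defined when some cells have no within-group partner. The
statistic requires at least two groups with at least two cells each.

During tuning the grouping is the top-label assignment *at that s* — no
external truth is needed — and `tune_label_weight()` reports homogeneity
and an ambiguity count per grid point, with `best_s` the grid argmax
(ties break toward smaller `s`). When ground truth exists (simulations) a
`groups =` argument scores against it instead; both modes are tested.

## Parameters that matter

| parameter | default | rationale |
|---|---|---|
| restart probability `α` | 0.5 | midpoint of the 0.4–0.6 range in which diffusion encodes graph structure with little variation; exposed, not tuned |
| label edge weight `s` | tuned | grids of powers of ten: 1e−2..1e4 (real data), 1e−4..1e−1 (simulation protocol) |
| promoter window | 2000 bp upstream of TSS | standard ATAC practice; strand-aware, clipped at 0 |
| binarization threshold | count > 0 | any signal marks a bin/peak accessible |
| ambiguity quantile | 0.10 | a cell is ambiguous when its top-two score gap is in the bottom decile of gaps |
| linkage for label clustering | complete | the default of the standard agglomerative routine; configurable |
| enrichment resamples | 10 000 | empirical-p resolution ~1e−4 with add-one correction |

## The synthetic-data generator

`simulate_two_types()` emulates high-quality scATAC-seq after binned
preprocessing: per-cell total reads are lognormal with median 5500
(σ = 0.5; an empirical depth list can be substituted), spread
multinomially over `p` bins (default 2000) by a global propensity drawn
once per seed from a symmetric Dirichlet(0.5) — a stand-in for the
unavailable real reads-per-bin distribution. Types are made distinct by
splitting bins half/half by index and adding a fixed percentage of extra
reads (1/5/10% = low/medium/high) over the cell's type's half. The extra
reads are spread *uniformly* over that half: spreading them by the
restricted propensity instead puts them on bins the base reads already
occupy, so after binarization the within/between Jaccard contrast is
exactly zero at every concentration we tested and the distinctness knob
does nothing. Uniform extras produce the expected low/medium/high
separability ladder.

Labeling draws an exact `round(frac · n)` cells without replacement for
correct weight-1 edges and an independent draw for wrong-label edges (a
cell can hold both). Read noise removes `⌊pct%⌋` of each cell's reads
uniformly from the read multiset, or adds the same count multinomially by
the global propensity. Mixture populations draw reads from a blend
`(1 − w)·global + w·uniform(type's bins)` and carry no label edges.

What the generator does **not** emulate: fragment-length structure, TSS
enrichment, doublets, batch effects — and, importantly, real sparsity.
5500 reads over 2000 bins leaves ~60% of bins occupied, far denser than
genome-wide binned scATAC, so cell–cell Jaccard values sit near 0.7 and
absolute homogeneity values are small and not comparable across data of
different sparsity. A green simulation test therefore establishes that
the machinery ranks configurations correctly (more distinct types, fewer
mislabels, tolerable read noise), not that any absolute homogeneity or
accuracy value transfers to real data. One concrete consequence: the
label-weight transition happens near mass ratio `s ≈ 1` here, so on the
simulation grid 1e−4..1e−1 homogeneity increases monotonically toward the
upper end rather than peaking strictly inside; the interior optimum is
visible once the grid extends to ~1e1 and beyond.

## Numerical and procedural choices

* Dense solve of the full `q × q` system up to a 20 000-node cap; above
  it, sparse LU computes only requested columns (the applications need
  label columns plus cell subsets). Row-sum tolerance 1e−8.
* Deterministic tie-breaks everywhere: top-label ties go to the earlier
  label (and are counted), tuning ties to the smaller `s`, nearest-gene
  ties to the smaller TSS coordinate.
* Empirical p-values use the add-one correction,
  `(1 + #{null ≥ obs}) / (N + 1)`, so `p = 0` is impossible.
* Region permutations relocate each region uniformly within its
  chromosome, preserving lengths and pairwise non-overlap by rejection
  sampling (an optional excluded-interval set is honored); a region
  longer than its chromosome is fatal.
* z-scoring of label scores uses the sample standard deviation; a label
  with identical influence on all cells yields an all-zero column rather
  than being dropped, keeping label indices stable. Rows are rescaled to
  a maximum of 1 only when the maximum is positive.
* Region-to-label mapping uses raw (not z-scored) cell-to-label
  influence, matching the definition of the bulk-mapping sum; score
  normalization is available separately through `label_scores()`.
* MTX orientation is resolved by matching declared dimensions against
  barcode/feature counts; a square matrix is ambiguous and requires an
  explicit flag — silent transposition is the classic single-cell bug.

## Known limitations

* All genomic input must be BED-dialect 0-based half-open; GTF is not
  parsed.
* The permutation null for the bimodality test recomputes correlations
  per permutation and is O(n_perm · peaks); it is meant for hundreds of
  regions, not tens of thousands.
* The homogeneity-vs-`s` curve in the bundled simulation world peaks at
  `s ≥ 1` (see above); on sparser real data the transition, and hence the
  useful grid, sits lower.
* Mixture populations are generated from exactly two base types.
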