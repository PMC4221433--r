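---
title: "heatcraft: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{heatcraft: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

heatcraft renders expression-style numeric tables (genes × conditions,
compounds × targets, and the like) as clustered, publication-quality
heatmaps, entirely from scripts. This vignette documents the model behind
each stage, the tunable parameters and their defaults, the numerical
conventions, and the places where the design was genuinely open and a
choice had to be made.

## The pipeline

```{r, eval = FALSE}
read_sheet() |> auto_fill()          # or select_area()
  |> normalize_table()               # linear or log min-max, global
  # pairwise_dist() + hier_cluster() / kmeans_metric() on either axis
  |> compose_heatmap()               # raster with dendrograms + color bar
  |> export_figure()                 # PNG / TIFF, dpi in metadata
```

`run_heatmap()` drives the whole chain from a single declarative
configuration and writes a sidecar JSON report containing every effective
parameter, the global min/max, clustering seeds and leaf orders — the
report alone is sufficient to reproduce the figure byte for byte.

## Input model

A sheet (CSV, TSV, or the first worksheet of an XLS/XLSX file) is read as a
rectangular grid of text cells; ragged rows are right-padded. The numeric
data area is selected with 1-based inclusive coordinates, exactly as a
spreadsheet user would quote them; `auto_fill()` encodes the common
convention that the first row and first column hold the X- and Y-axis
labels. Every cell of the data area must parse as a finite decimal number
(integer, decimal or scientific notation, `.` as decimal mark, no locale
handling). A blank or textual cell is a hard error naming the sheet
coordinate: imputing values into a figure silently would misrepresent the
data, and no principled default exists at this layer. Duplicate labels are
preserved verbatim — gene lists legitimately repeat symbols.

## Normalization

Both modes rescale globally over the whole matrix (not per row): the heatmap
is meant to compare all cells against one color scale, and the global
minimum and maximum are what the color-bar endpoints annotate.

* **Linear**: `NV = (OV − Min) / (Max − Min)`.
* **Log**: `NV = (log_a OV − log_a Min) / (log_a Max − log_a Min)`,
  defined only for strictly positive values. The default base is `a = 2`
  (the convention for expression ratios), with `10`, `e`, or any positive
  base ≠ 1 accepted. By change of base the ratio is algebraically
  independent of `a` (the tests verify agreement across bases to 1e-12), so
  the base matters only for how a reader interprets the color-bar
  annotation. Had the intent instead been to display raw log-transformed
  values without rescaling, behavior would differ; the min–max form is the
  only one consistent with requiring `Max ≠ Min` and producing a [0, 1]
  range for color lookup.

`Max = Min` is detected by exact floating-point equality: inputs are
finite parsed decimals, and an epsilon would only blur a condition that is
structural (a constant matrix has no color range), not numerical.

## Color lookup table

A color scale is an ordered list of at least two RGB anchors; the default
tricolor is green `(0,255,0)` → black → red `(255,0,0)`, the microarray
convention for low/mid/high expression. The scale is discretized into
exactly **768 rows × 3 channels** (a 256-level color mode per channel,
summed over three channels) by piecewise-linear interpolation in RGB
space. The 767 inter-row steps are divided as evenly as possible among the
anchor segments, with remainder steps assigned to earlier segments — the
decomposition across segments is not otherwise constrained, so the simplest
deterministic rule was chosen. Channel values are rounded half-up
(`floor(x + 0.5)`), a locale-free rule with no ties-to-even surprises.

A normalized value selects row `round_half_up(NV × 767) + 1`; values
outside [0, 1] are an error rather than clamped, because normalization
already guarantees the range and silent clamping would mask upstream bugs.
Interpolation in a perceptually uniform space (Lab/LCh) was deliberately
left out: the 768-row RGB table *is* the color model here, and its contents
are part of the engine's contract.

## Distances

Seven metrics over the row or column vectors:

| metric | definition |
|---|---|
| euclidean | `sqrt(sum((x - y)^2))` |
| squared_euclidean | `sum((x - y)^2)` |
| manhattan | `sum(abs(x - y))` |
| maximum | `max(abs(x - y))` |
| pearson | `1 − r(x, y)` |
| spearman | `1 − ρ(x, y)`, average ranks for ties |
| kendall | `1 − τ_b(x, y)`, tie-corrected |

The correlation distances use the plain `1 − coefficient` form (range
[0, 2]), not `(1 − coefficient)/2`: "Pearson distance" conventionally means
the former. Kendall is τ_b, computed by direct O(n²) pair counting —
expression matrices contain ties, and a tie-naive τ_a would miscount them;
vector lengths here are heatmap axis lengths, so the quadratic loop is
never the bottleneck. A constant vector under a correlation metric is a
domain error (the coefficient is undefined); the message suggests removing
or jittering the flat row rather than inventing a distance. The test suite
cross-checks all three coefficients against `stats::cor()` on random
vectors and on tied data.

## Hierarchical clustering

Agglomeration is the naive definition made explicit: start from singletons
and repeatedly merge the pair of clusters with the smallest linkage
distance, where the linkage is recomputed **directly from the original
pairwise distances** — average = mean over all cross pairs (UPGMA, not the
weighted WPGMA variant), minimum = closest cross pair, maximum = farthest
cross pair. No Lance–Williams update formulas: the direct form is
transparent, trivially checkable against an independent implementation, and
fast enough at heatmap scale (the implementation caches the live linkage
matrix and recomputes only the merged cluster's entries, keeping the whole
run O(n³) with vectorized inner steps). All three criteria are reducible,
so merge heights are non-decreasing; the tests verify this, the
single-linkage/minimum-spanning-tree identity, and full dendrogram
equivalence with `stats::hclust()` across all 21 linkage × metric
combinations.

Ties in the merge choice are broken deterministically in favor of the pair
whose clusters contain the lexicographically smallest original indices —
reproducibility requires *some* rule, and original-index order is the only
one that does not depend on floating-point accidents.

The leaf order places, at every merge, the child subtree containing the
smaller minimum original leaf index on the left; `cut_tree(tree, k)` undoes
the last k − 1 merges and numbers components by first appearance along the
leaf order. Optimal leaf ordering (Bar-Joseph) is out of scope. A
`as.hclust()` method bridges to the standard R clustering utilities.

## k-means

`kmeans_metric()` is Lloyd-style with a pluggable metric: seeded sampling
of k distinct rows as initial centroids; assignment to the nearest centroid
under the chosen metric with ties to the lowest centroid index; centroid
update by arithmetic mean; an emptied cluster seizes the point farthest
from its current centroid (excluding points that are their cluster's sole
member). The mean is the cost-minimizing center only for squared Euclidean,
so cost convergence is guaranteed there (the per-iteration cost history is
recorded and tested to be non-increasing); under other metrics the
iteration cap `max_iter` (default 100) bounds the run and `n_iter` is
reported. The seed is a required argument and is recorded in the result and
the run report — there is no hidden global RNG state. If a centroid becomes
constant under a correlation metric the run aborts with advice to use a
geometric metric, rather than silently producing an undefined distance.

## Rendering and export

The canvas is assembled from closed-form components: four margins (default
10 px each), one 60 px gutter per requested dendrogram, the label areas
(sized from the 5×7 bitmap font: 6 px per character), an optional color bar
(12 px strip plus tick labels), and the cell grid (default 18 × 18 px
cells). Pixel coordinates are 0-based with the origin at the top left, and
cell rectangles are half-open so adjacent cells share no pixels; the center
pixel of every cell carries exactly the LUT color of its normalized value,
which the tests probe directly. "Rotation" is implemented as transpose
(axes, labels, titles and trees swapped) plus a column-label angle of 0, 45
or 90 degrees; free-angle canvas rotation is undefined for a cell grid and
excluded.

Text is rasterized with a package-defined 5×7 bitmap font. This is a
deliberate trade: no system font, font library or antialiasing means every
export is byte-identical across machines, at the cost of typographic
refinement.

The final canvas width and height are padded up to the next multiple of
6 px. This makes the export arithmetic exact: a figure is defined at
72 dpi, and exporting at dpi *d* resizes (nearest neighbor) to
`size × d/72` pixels, so the 300 and 600 dpi presets scale by the exact
rationals 25/6 and 50/6 and differ by exactly 2×. The dpi is recorded in
the PNG pHYs chunk and in TIFF XResolution/YResolution tags. TIFF files
are written by a minimal built-in baseline writer (single uncompressed RGB
strip, little-endian, resolution tags); PNG uses a fixed compression level.
Neither embeds timestamps. Vector formats and cell-text annotation are out
of scope.

## The synthetic-data generator

`generate_synth()` emulates the shape of the matrices this kind of tool is
pointed at — tens-to-hundreds of rows falling into a few co-regulated
groups across a handful of conditions. Each of `n_groups` row groups gets a
step profile elevated by `effect × noise_sd` over its own block of columns
(orthogonal across groups), plus i.i.d. Gaussian noise; defaults are 60 × 6
with 3 groups, `effect = 8`, `noise_sd = 1`. `positive_shift` (default on)
shifts the matrix so the minimum is ≥ 0.1, keeping log normalization
applicable; `ties` rounds to one decimal to inject the duplicate values
that exercise average-rank Spearman and τ_b. Everything is determined by
the required seed.

What it does **not** emulate: count-distribution noise (negative binomial
overdispersion), heavy tails, missing values, correlated noise between
conditions, or batch structure. Passing the recovery tests (mean adjusted
Rand index ≥ 0.9 at `effect = 10` over 20 seeds, at 60 × 6 with three
groups of 20) therefore demonstrates that the clustering machinery is
correct and well-conditioned, not that real single-cell or proteomics data
will cluster as cleanly.

## Problem sizes in the tests

The suite favors many small, fully-checkable instances: dendrogram oracle
equivalence on 100 random instances of up to 8 items across all 21
linkage × metric combinations; 200 random matrices for the normalization
properties; 20 seeded simulations for cluster recovery; 20 random figures
for pixel probing. These sizes give exhaustive coverage of the branch
structure (ties, remainders, endpoint cells) while keeping a full run in
the tens of seconds; the algorithms themselves are routinely used at a few
hundred rows, where a clustering completes in well under a second.

## Known limitations

* `.xls`/`.xlsx` reading takes the first worksheet only, and Excel numeric
  cells pass through a text conversion, so values with more than ~15
  significant digits may lose precision there (CSV/TSV round-trips are
  exact by construction).
* The 45° label angle uses a nearest-neighbor rotation of the bitmap font
  and is legible but not pretty.
* Correlation metrics require ≥ 2 conditions and non-constant vectors;
  matrices with flat rows must be filtered or given a geometric metric.
* k-means under non-Euclidean metrics is a heuristic (mean centroids); it
  is provided for parity, with squared Euclidean the recommended default.
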