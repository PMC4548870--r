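---
title: "Overlap-based cell tracking: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overlap-based cell tracking: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(masktrack)
```

## The tracking model

`masktrack` links segmented cells across a time-ordered series of label
masks. Its operating premise is physical, not statistical: at acquisition
intervals of roughly 5–15 minutes, a cultured mammalian cell moves a small
fraction of its own diameter between frames, so its two consecutive
instances occupy overlapping pixels. Pixel overlap is therefore the primary
evidence that two regions are the same cell; centroid displacement and
size change refine the decision when several cells overlap or when overlap
alone is ambiguous.

Every candidate link from source cell $c_i^k$ (frame $k$) to target cell
$c_j^{k+1}$ is scored by

$$d(c_i^k, c_j^{k+1}) = w_o\, O + w_c\, \delta_c + w_s\, \delta_s,$$

a weighted sum of three independent metrics, each normalized to $[0, 1]$
with $0$ meaning a perfect match:

* **Overlap metric** $O = 1 - \tfrac{n_o}{2}\bigl(\tfrac{1}{s_i} +
  \tfrac{1}{s_j}\bigr)$, where $n_o$ is the number of pixels the two cells
  share (counted at identical coordinates, no registration) and $s_i, s_j$
  are their areas in pixels. $O = 0$ only when both cells consist of
  exactly the same pixels; $O = 1$ when they share none. The form averages
  the two one-sided overlap fractions, so a small cell engulfed by a large
  one is still penalized for the unexplained area of the larger cell.
* **Centroid metric** $\delta_c = \lVert (X_i, Y_i) - (X_j, Y_j) \rVert /
  \sqrt{I_h^2 + I_w^2}$. Normalizing by the image diagonal is the one
  choice that makes a full-diagonal displacement score exactly 1 and keeps
  the metric inside $[0,1]$ for any in-frame pair. Centroids are
  unweighted means of member pixel coordinates — the standard reading for
  binary regions.
* **Size metric** $\delta_s = |s_i - s_j| / \max(s_i, s_j)$, the relative
  area change; it is 0 for equal areas and strictly below 1 always.

The sum form keeps the terms independent: a criterion can be reweighted or
a new term added without touching the others.

## Pathological filtering

Before costing, a pair with **zero** shared pixels whose *raw* centroid
distance (in pixels, not the normalized $\delta_c$) exceeds
`max_centroid_distance` is assigned the sentinel `max_cost` and declared
invalid — a cell in one corner of the field is never a candidate for a
cell in the opposite corner. Two deliberate readings are baked in:

* the rule is **conjunctive**: any shared pixel keeps a pair valid no
  matter how far the centroids are (a long thin cell can have a distant
  centroid yet genuinely overlap);
* the threshold applies to the raw pixel distance, because it expresses a
  physical bound on cell motion per frame, which should not silently
  change with image size.

## Choosing the links: global assignment

For each consecutive frame pair the full cost matrix is solved as a global
minimum-cost bipartite assignment rather than greedily: among matchings
that exclude invalid pairs, the solver first maximizes the number of
links, then minimizes their total cost. Cardinality must dominate —
otherwise the empty matching (total cost 0) would always "win" — and it
encodes the biological prior that cells rarely vanish between frames.
Splits and merges (mitosis, collisions) are out of scope: the matching is
strictly one-to-one, and a dividing cell will start one new track.

The solver is a Jonker–Volgenant shortest-augmenting-path assignment on a
square augmentation of the rectangular matrix: each source gets a private
slack column and each target a private slack row, priced above the total
finite cost, so staying unmatched is always feasible but never preferred
over a valid link. An exhaustive enumerator (`brute_force_mapping()`)
implements the identical objective by depth-first search and serves as the
independent oracle in the test suite.

**Tie-breaking.** Real-valued costs tie only on degenerate inputs, but the
output must still be deterministic. Among equal-cost optima the mapping
chosen is the lexicographically smallest by source label, then target
label. The enumerator gets this for free from its search order; the
assignment solver applies a cost-neutral canonicalization pass afterwards
(swapping links whenever doing so lowers the lexicographic order without
changing total cost, with an equality tolerance of $10^{-9}$, far below
any meaningful cost difference).

## From links to tracks

Chaining is purely mechanical: every cell of frame 1 seeds a track, a link
extends a track, an unmatched target starts the next track number, an
unmatched source ends its track. Track numbers are assigned in order of
first appearance (frame, then label), giving ids $1..T$ with no gaps. A
terminated track never resumes: if a cell leaves the field (or
segmentation drops it) and returns, it returns as a new track — no
gap-closing model is implied by the cost function, so none is invented.

Relabeling rewrites each mask so a cell's pixels carry its track id in
every frame ("same cell, same number"); geometry is untouched, which the
tests check as conservation of the per-frame multiset of region sizes.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `weight_overlap` ($w_o$) | 2 | — | overlap is the principal, most reliable evidence |
| `weight_centroid` ($w_c$) | 1 | — | resolves competition among overlapping candidates |
| `weight_size` ($w_s$) | 0.5 | — | areas fluctuate with focus/segmentation; weakest evidence |
| `max_centroid_distance` | 50 | px | generous bound on per-frame motion at 5–15 min intervals |
| `max_cost` | $10^9$ | — | any sentinel strictly above $w_o + w_c + w_s$ is equivalent |
| `frame_interval_min` | 15 | min | converts path length to travel rate |

Raising $w_o$ suits faster acquisition (more overlap); raising $w_s$ suits
cell lines with stable areas. Weights are free parameters, never
auto-tuned.

## The synthetic-data generator

`simulate_sequence()` emulates the input the tracker is designed for:
segmented masks of fibroblast-like cells imaged fast enough that each cell
overlaps its own previous footprint. Cells are discretized ellipses with
semi-axes drawn from `cell_radius_range`, placed and kept **non-touching**
(segmentation is assumed to have separated cells; colliding cells are out
of scope, so the generator maintains a safety gap). Centers follow a
uniform random walk with per-axis steps in $[-\texttt{max\_step},
\texttt{max\_step}]$, reflecting at the borders; areas may jitter within
`size_jitter` of the base area; cells can permanently disappear or newly
appear with per-frame probabilities. Per-frame labels are randomly
permuted — essential, because it verifies that tracking never leans on the
arbitrary per-frame numbering.

The defaults describe the study condition used throughout the tests: a
520 × 696 px frame, 10 cells of semi-axes 8–14 px, 25 frames, `max_step =
4` px (half the smallest semi-axis, which geometrically guarantees
self-overlap in every consecutive pair), no size jitter, no
births/deaths. Under these conditions the tracker must — and the
acceptance suite checks that it does — recover every ground-truth identity
across multiple seeds. A property test also checks the converse trend:
with steps far beyond the cell diameter the premise collapses and the
score drops.

What the generator does **not** emulate: touching/overlapping cells,
segmentation errors (split, merged or missing regions), mitosis, irregular
shapes, intensity information. Passing on synthetic data therefore
demonstrates correctness of the linking machinery under the method's
stated premise, not robustness to segmentation failure on real images.

## Numerical and I/O choices

* Masks are integer matrices; coordinates are 0-based `(row, col)` with
  the centroid exported as `x` = column, `y` = row. Pixels of one label
  need not be connected — a cell is *defined* as the set of equal-valued
  pixels; repairing connectivity is segmentation's job.
* Canonical labels are $\{1..M\}$. `canonicalize_labels()` leaves an
  already-consecutive numbering as stored (per-frame numbers carry no
  identity, and rewriting them would break external ground-truth
  references); gapped or arbitrary labels are renumbered by first
  encounter in a raster scan.
* Output masks are 16-bit grayscale TIFF (track counts exceed 255); PNG is
  accepted on input at 8 or 16 bit and written at 8 bit only. Stored
  sample values are the labels themselves, so write/read round trips are
  pixel-exact.
* Frame order comes from natural (numeric-aware) filename sorting, not
  file metadata.
* Degenerate inputs: an empty frame yields a cost matrix with zero
  rows/columns and every cell of the opposite frame unmatched; an all
  `max_cost` matrix yields no links; a sequence needs at least two frames.

## Problem sizes used in the tests

Unit and property tests run on small scenes (frames up to 300 × 500 px,
up to 10 cells, up to 25 frames; 40–300 random assignment instances with
the smaller matrix dimension at most 6–7; 2,000–10,000 random metric
evaluations), chosen so the whole suite and the acceptance script each
complete in seconds while still exercising every code path at the full
default frame size.

## Known limitations

* No mitosis, fusion or collision handling; strictly one-to-one links.
* No gap closing; occlusion or a dropped segmentation splits a track.
* No shape term in the cost; morphologically stable objects that swap
  positions while overlapping can in principle be confused.
* Quality is bounded by segmentation quality: the tracker never edits
  region geometry.
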