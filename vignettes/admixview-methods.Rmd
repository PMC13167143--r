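---
title: "Methods: aligned structure-plot grids in admixview"
author: "admixview authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aligned structure-plot grids in admixview}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixview)
```

## The data model

A clustering run on genotype data at a fixed K yields an N×K membership
matrix Q: row *i* holds individual *i*'s estimated ancestry proportions
across K latent clusters and sums to 1. Alignment tools (Clumppling,
Pong) group runs into *modes* — distinct solutions per K — and align
cluster labels both within and across K. `admixview` consumes the
*output* of that alignment; it never runs clustering or alignment
itself, and alignment costs, when supplied, are taken as given.

Three assumptions are inherited from the aligned input:

1. **Shared individuals.** Every mode's matrix has the same N rows in
   the same order.
2. **Aligned cluster indices.** Cluster *c* denotes the same inferred
   cluster in every mode with k ≥ c; a mode with k < Kmax simply lacks
   the higher indices. This is the premise of aligned input; the
   package assumes aligned indices form a consistent prefix and does
   not attempt to verify biological identity.
3. **Rank-by-support mode labels.** `K{k}M{m}` means the m-th most
   supported mode at K = k; within each K, run counts are
   non-increasing in mode rank (enforced by `ModeBundle` validity).

Rows of every parsed matrix are rescaled to sum exactly to 1 when their
raw sum is within `normalizeTol` of 1 (default 0.05 — upstream tools
print rounded proportions, so small deviations are rounding, while
larger ones signal a wrong file and are an error).

## View state and transforms

All display decisions live in one `ViewState`: cluster stack (stored
bottom-up), population order, individual order, palette, highlight,
display toggles, cluster display names. Every interactive feature is a
pure function `(bundle, state, args) -> state`, so figures are
reproducible and a state serialized to JSON replays byte-identically.

**Dominance sorting.** For each population P (in the current population
order), the dominant cluster is `argmax_c sum_{i in P} Q[i, c]` on the
chosen reference mode; ties take the lowest cluster index. Individuals
within P are sorted by descending membership in that cluster, ties by
original index. Because the result depends only on (reference mode,
labels, population order) — not on the current individual order — the
operation is idempotent, and the single resulting permutation is
applied to every mode at render time. Equal-membership runs are kept in
original-index order; a stable sort is this package's documented
contract where upstream behavior is unobservable.

**Population grouping.** Label files may interleave populations;
rendering always groups individuals into contiguous population blocks
following the population order (block grouping is what makes x-axis
labels and separators meaningful), preserving relative order within
blocks. When no labels are supplied, all individuals form one
pseudo-population `"ALL"`, and population reordering is a
feature-disabled error rather than a silent no-op.

**Highlighting** dims non-highlighted segments to 25% opacity
(highlighted segments stay at 100%); the dimming factor is a package
choice, applied uniformly so that toggling a highlight changes only
opacity attributes, never geometry.

## Layout and edges

Modes are placed on a grid: rows are K values ascending top-to-bottom,
the column of a mode is its rank, so the major mode of the smallest K
sits in the upper-left corner. Rows with fewer modes are left-aligned
(centering is a plausible alternative; left-alignment keeps cell
coordinates a pure function of (K rank, mode rank)). Only edges joining
two visible modes whose K values differ by exactly 1 are drawn —
alignment files may list all pairs, and the display is defined on
adjacent K. Edge darkness maps cost linearly over the drawn edges'
range: best cost → opacity 1.0, worst → 0.15. The floor keeps the worst
edge visible (an invisible "shown" edge would contradict the edge
toggle's semantics); a degenerate range maps to 1.0. Edge anchors run
from the bottom-center of the upper cell to the top-center of the lower
cell, fanned out horizontally by the partner's column (8 units per
column) so parallel edges do not overlap.

## Rendering

Each mode is a stacked barplot: one bar per individual, segments
stacked bottom-up along the cluster stack restricted to the mode's k,
segment height proportional to membership so every bar fills the cell
height exactly. Default geometry: plot width `max(N, 240)` units (one
unit per individual with a floor for legibility), height 80, gaps
40/60, PNG at 200 DPI — all overridable. Population labels rotate 45°
when their block is narrower than the estimated label width. The
legend is a separate document listing clusters in stacking order, top
of the plot first.

Determinism is a hard contract: all numeric attributes are emitted at
fixed precision (2 decimals for coordinates, 3 for proportions in
tooltips), there are no timestamps and no randomness, so identical
(bundle, state) inputs yield byte-identical SVG. Fixed 2-decimal
coordinates bound the per-bar height rounding error by 0.005·K ≪ 0.5
user units. Every segment carries `data-mode`/`data-ind`/`data-cluster`
annotations and every bar embeds a `<title>` tooltip, which is what the
interactive HTML export and the structural tests hook into.

PNG files are produced by redrawing the identical scene geometry (kept
alongside the SVG text in the `RenderedFigure`) on R's cairo `png()`
device at the requested DPI. The byte-identity guarantee applies to
the SVG; PNGs are same-geometry rasters whose bytes may vary across
cairo versions.

The default palette is a fixed 12-color colorblind-safe qualitative
cycle (Paul Tol's "safe" scheme). Beyond 12 clusters the cycle repeats
with lightened variants and a warning — renders stay reproducible, but
color uniqueness is no longer guaranteed.

## File dialects

* **clumppling**: files `K{k}M{m}.Q`/`.txt`; optional `modes.txt`
  (`label count`) for run counts, default 1; optional `labels.txt`,
  `alignments.txt`.
* **pong**: `filemap.txt` with lines `runid K path`. Pong's exact
  layout varies by version, so the contract is explicit: rows
  sharing a matrix file are runs of one mode; modes within a K are
  ranked by run count, ties keeping filemap order.
* **plain**: an explicit `manifest.json` array of
  `{"label", "path", "runs"}` — the escape hatch for any other tool.

Duplicate unordered mode pairs in an alignment file keep the last
occurrence (upstream files may append refinements) with a warning.
Indices are 1-based throughout, matching R convention; file lines are
reported 1-based in error messages.

## The synthetic generator

`generateBundle()` emulates the *input contract* of an aligned
analysis, not the biology:

* population centers at Kmax drawn from a flat Dirichlet; individuals
  from Dirichlet(center × `concentration`). `concentration` (default
  50) controls within-population spread: ~50 gives visibly admixed
  individuals, values in the thousands approach the point-mass limit
  where every individual sits on its population center;
* each lower-K major mode merges the two most-correlated columns of
  the major mode one K above (summing them; higher columns shift down
  one index), so cluster identity nests across K and the merge is
  exact — adjacent major modes have alignment cost 0 up to float
  round-off;
* minor modes take an alternative (next-ranked) merge plus a
  simplex-preserving perturbation (`noise`, default 0.05: a convex
  mixture with a flat Dirichlet draw, rows renormalized);
* alignment costs are the mean absolute difference between the lower-K
  matrix and the higher-K matrix with its best merge collapsed (brute
  force over merge pairs). This is a synthetic-only stand-in with the
  right qualitative behavior (0 for exact merges, growing with noise),
  not any upstream tool's cost formula;
* run counts: either drawn from the seed, or — via `runsPerK` — a
  stated per-K total partitioned deterministically with a strict
  maximum at rank 1. `runsPerK` exists so a generated bundle can
  reproduce a stated study design such as 8 runs per K over K = 2..8
  (56 runs, 11 modes), the scale used by the acceptance checks
  together with 2,426 individuals in 26 populations.

What the generator does **not** emulate: linkage, genotyping noise,
label switching (input is already aligned by construction),
non-nested modes, or realistic population divergence. Passing tests
therefore demonstrate the correctness of parsing, transforms, layout
and rendering on well-formed aligned input — not robustness to
misaligned or pathological upstream output, which is rejected by
validation rather than repaired.

The default spec (4 populations × 50 individuals, K = 2..5, one minor
mode, concentration 50) is sized so that the full test suite, which
regenerates every fixture in code, runs in seconds; the
block-recovery calibration uses concentration 10⁴ — the
point-mass regime where each individual's own argmax should agree with
its population block's dominant cluster in ≥ 95% of individuals.

## Transform order at the CLI

A batch CLI must fix what the interactive tool leaves free: transforms
apply as cluster reorder → population reorder → dominance sort →
highlight/rename/palette → display filters. Dominance sorting runs
after population reordering so blocks follow the requested order. The
final state is written beside the outputs and replays the figure
byte-identically.

## Known limitations

* No live zoom/pan or drag-and-drop; the HTML export implements only
  hover-highlight and edge/label toggles.
* Cluster identity across K is trusted, never re-verified against the
  matrices.
* The alignment-cost scale is treated as ordinal (only the min–max
  range matters for darkness); costs from different upstream tools are
  not comparable across files.
* Very large N makes per-individual SVG elements heavy; the raster
  export is the practical format there.
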