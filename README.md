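# admixview

Grid visualization of aligned population-structure clustering modes.

## The problem

Model-based clustering of multilocus genotype data (Structure, ADMIXTURE)
returns, for each run, an N×K membership matrix Q whose row *q&#8407;ᵢ* gives
individual *i*'s estimated ancestry proportions in K latent clusters
(rows sum to 1). Repeated runs disagree — label switching, multiple
optima, different K — so alignment tools (Clumppling, Pong, Clumpak,
CLUMPP) group runs into **modes**: distinct solutions per K, ranked by
how many runs support them (M1 = major mode), and aligned across K so a
cluster index means the same inferred cluster everywhere.

`admixview` takes those aligned results — one Q matrix per mode,
optional mode-pair alignment costs, optional per-individual population
labels — and renders the standard grid-of-structure-plots view: rows
are K values, columns are modes within a K, each plot a stacked barplot
of membership coefficients, with alignment edges between adjacent-K
modes drawn darker the better the alignment. The interactive-figure
operations are exposed as pure transforms on an explicit `ViewState`:

* **dominance sorting** — within each population, order individuals by
  descending membership in the cluster with the largest total
  membership in that population (computed on a chosen reference mode,
  propagated to every plot);
* population and cluster-stack reordering, cluster highlighting and
  renaming, palette overrides, minor-mode filtering, edge and label
  toggles.

Output is deterministic annotated SVG (plus PNG rasters and a separate
cluster legend), an optional self-contained interactive HTML document,
and a JSON view state that replays a figure byte-identically. A
Dirichlet-based synthetic generator produces complete aligned bundles
for testing and demos. Intended users: population geneticists preparing
publication structure-plot figures from Clumppling/Pong output, and
anyone needing scripted, reproducible versions of those figures.

## Worked example

```r
library(admixview)

# a synthetic aligned bundle: 4 populations x 50 individuals,
# K = 2..5, one minor mode at K = 4
b <- generateBundle(synthSpec(seed = 1))
b
#> ModeBundle: 5 modes over K = {2,3,4,5}, 200 individuals, 4 populations,
#>   20 total runs, 5 alignment edges

# sort individuals by cluster dominance on mode K5M1 and render
s <- sortByClusterDominance(b, "K5M1", defaultView(b))
head(indOrder(s), 10)
#> [1] 14 18 46  6 49  5 31 48 27 36

cat(tooltipText(b, "K5M1", indOrder(s)[1], s))
#> Individual 14 (POP1)
#> Cluster 5: 0.313
#> Cluster 4: 0.007
#> Cluster 3: 0.008
#> Cluster 2: 0.643
#> Cluster 1: 0.029

fig <- renderFigure(b, s)
exportFigure(fig, "figure")   # figure.svg, figure.png, figure_legend.png
```

The summary says the bundle holds 5 aligned modes over K = 2..5 backed
by 20 clustering runs. The individual order starts with individual 14:
within population POP1, it has the highest membership in that
population's dominant cluster. The tooltip lists the memberships in the
current stack order (top of the plot first).

The same pipeline from a shell, via the bundled script
(`inst/cli/admixview`, installed under the package's `cli/` directory):

```sh
admixview simulate --out demo_bundle --seed 1
admixview summarize --input demo_bundle
# individuals:  200
# populations:  4
# modes:        5
# K values:     2, 3, 4, 5
# total runs:   20
admixview render --input demo_bundle --sort-by K5M1 --highlight 2 --out demo
```

`render` writes `demo.svg`, `demo.png`, `demo_legend.png`, and
`demo_state.json`; re-running with `--state demo_state.json` reproduces
the SVG byte for byte.

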