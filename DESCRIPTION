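Package: admixview
Title: Grid Visualization of Aligned Population-Structure Clustering Modes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reads aligned population-structure clustering results (one
    membership matrix per clustering mode, optional mode-pair alignment
    costs, optional per-individual population labels), applies the standard
    interactive-figure transforms (per-population dominance sorting,
    cluster and population reordering, cluster highlighting and renaming,
    minor-mode filtering, palette customization) as pure operations on an
    explicit view state, lays the modes out on a K-by-mode grid with
    cost-weighted alignment edges, and renders deterministic annotated SVG
    plus PNG structure-plot figures, a separate cluster legend, and an
    optional self-contained interactive HTML document. Includes a synthetic
    bundle generator emulating aligned Admixture-style output and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    jsonlite,
    grDevices,
    grid,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
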