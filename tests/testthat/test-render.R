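# pull numeric attribute values out of SVG text
attrVals <- function(svg, attr, tag = "rect") {
  pat <- sprintf('<%s[^>]*? %s="([0-9.]+)"', tag, attr)
  m <- gregexpr(pat, svg)
  hits <- regmatches(svg, m)[[1]]
  as.numeric(sub(pat, "\\1", hits))
}

test_that("segments stack proportionally, cluster 1 at the bottom", {
  b <- ModeBundle(list(Mode(2, 1, 1, rbind(c(0.25, 0.75)))))
  s <- defaultView(b)
  svg <- renderStructurePlot(bundleModes(b)[[1]], s, 0, 0, 10, 100)
  h <- attrVals(svg, "height")
  expect_equal(sort(h), c(25, 75))
  y <- attrVals(svg, "y")
  # cluster 1 (height 25) occupies the bottom: y = 100 - 25 = 75
  expect_equal(y[h == 25], 75)
  expect_equal(y[h == 75], 0)
})

test_that("identical rows render identical bars", {
  Q <- rbind(c(0.4, 0.6), c(0.4, 0.6))
  b <- ModeBundle(list(Mode(2, 1, 1, Q)))
  svg <- renderStructurePlot(bundleModes(b)[[1]], defaultView(b), 0, 0, 20, 50)
  h <- attrVals(svg, "height")
  expect_equal(h[1:2], h[3:4])
  expect_error(
    renderStructurePlot(bundleModes(b)[[1]], defaultView(b), 0, 0, 0, 50),
    class = "avValueError")
})

test_that("per-bar segment heights sum to the cell height within 0.5 units", {
  set.seed(23)
  b <- generateBundle(synthSpec(
    populationSizes = c(A = 10, B = 10), kValues = 2:4, modesPerK = 2,
    seed = 8))
  s <- defaultView(b)
  fig <- renderFigure(b, s, plotWidth = 60, plotHeight = 80)
  bars <- extractBars(fig@svg)
  expect_length(bars, 6 * 20)  # one bar per individual per mode
  for (bar in bars) {
    expect_lt(abs(sum(attrVals(bar, "height")) - 80), 0.5)
  }
})

test_that("figure structure reflects modes, edges, and toggles", {
  b <- tinyBundle()
  s <- defaultView(b)
  fig <- renderFigure(b, s, plotWidth = 30)
  expect_equal(countMatches('class="structure-plot"', fig@svg), 3L)
  expect_equal(countMatches('<g class="edges">', fig@svg), 1L)
  expect_equal(countMatches("<line x1", fig@svg), 2L)
  expect_equal(countMatches('class="mode-label"', fig@svg), 3L)

  s2 <- s; s2@hideMinorModes <- TRUE
  fig2 <- renderFigure(b, s2, plotWidth = 30)
  expect_equal(countMatches('class="structure-plot"', fig2@svg), length(kValues(b)))

  s3 <- s; s3@showEdges <- FALSE
  fig3 <- renderFigure(b, s3, plotWidth = 30)
  expect_equal(countMatches("<line x1", fig3@svg), 0L)

  s4 <- s; s4@showModeLabels <- FALSE
  fig4 <- renderFigure(b, s4, plotWidth = 30)
  expect_equal(countMatches('class="mode-label"', fig4@svg), 0L)
})

test_that("rendering is deterministic and SVG is well-formed XML", {
  b <- tinyBundle()
  s <- defaultView(b)
  f1 <- renderFigure(b, s, plotWidth = 30)
  f2 <- renderFigure(b, s, plotWidth = 30)
  expect_identical(f1@svg, f2@svg)
  expect_identical(f1@legendSvg, f2@legendSvg)
  doc <- xml2::read_xml(f1@svg)
  expect_identical(xml2::xml_name(doc), "svg")
  xml2::read_xml(f1@legendSvg)  # errors if malformed
})

test_that("highlight changes only opacity attributes, never geometry", {
  b <- tinyBundle()
  s <- defaultView(b)
  plain <- renderFigure(b, s, plotWidth = 30)@svg
  lit <- renderFigure(b, highlightCluster(s, 2), plotWidth = 30)@svg
  stripOp <- function(x) gsub('fill-opacity="[0-9.]+"', "", x)
  expect_false(identical(plain, lit))
  expect_identical(stripOp(plain), stripOp(lit))
  # non-highlighted segments dimmed to 0.25, highlighted at 1
  ops <- unique(regmatches(lit, gregexpr('fill-opacity="[0-9.]+"', lit))[[1]])
  expect_setequal(ops, c('fill-opacity="0.25"', 'fill-opacity="1.00"'))
})

test_that("a cluster keeps one color across all plots and the legend", {
  b <- tinyBundle()
  s <- defaultView(b)
  fig <- renderFigure(b, s, plotWidth = 30)
  for (cl in 1:3) {
    pat <- sprintf('data-cluster="%d"', cl)
    rects <- regmatches(fig@svg,
      gregexpr(sprintf('<rect[^>]*fill="(#[0-9A-F]{6})"[^>]*%s', pat), fig@svg))[[1]]
    fills <- unique(sub('.*fill="(#[0-9A-F]{6})".*', "\\1", rects))
    expect_identical(fills, s@palette[cl])
    expect_match(fig@legendSvg, sprintf('%s"><title>Cluster %d</title><rect[^>]*fill="%s"',
                                        cl, cl, s@palette[cl]))
  }
})

test_that("legend lists clusters in current stacking order, top of plot first", {
  b <- tinyBundle()
  s <- reorderClusters(defaultView(b), c(3, 1, 2))
  fig <- renderFigure(b, s, plotWidth = 30)
  ids <- regmatches(fig@legendSvg,
    gregexpr('legend-entry" data-cluster="([0-9]+)"', fig@legendSvg))[[1]]
  expect_identical(as.integer(sub(".*\"([0-9]+)\"", "\\1", ids)), c(3L, 1L, 2L))
})

test_that("export writes SVG plus two PNGs and re-exports byte-identically", {
  b <- tinyBundle()
  fig <- renderFigure(b, defaultView(b), plotWidth = 30)
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "fig")
  files <- exportFigure(fig, prefix, dpi = 96)
  expect_identical(unname(files),
                   paste0(prefix, c(".svg", ".png", "_legend.png")))
  expect_true(all(file.exists(files)))
  svg1 <- readLines(files[["svg"]])
  exportFigure(fig, prefix, dpi = 96)
  expect_identical(readLines(files[["svg"]]), svg1)
  # PNG files are real rasters with content
  expect_gt(file.size(files[["png"]]), 200)
  expect_gt(file.size(files[["legend_png"]]), 200)

  err <- tryCatch(exportFigure(fig, file.path(dir, "no/such/dir/fig")),
                  error = identity)
  expect_s3_class(err, "avExportError")
  expect_match(conditionMessage(err), "stage")
})

test_that("interactive HTML is self-contained and embeds a faithful bundle", {
  b <- tinyBundle()
  s <- defaultView(b)
  f <- withr::local_tempfile(fileext = ".html")
  exportInteractiveHTML(b, s, f, plotWidth = 30)
  html <- paste(readLines(f), collapse = "\n")
  expect_false(grepl('src="|href="|url\\(|@import', html))  # no external resources
  expect_equal(countMatches('<g class="bar"', html), 6L * 3L)  # one tooltip per individual per mode

  json <- sub('.*<script type="application/json" id="bundle-data">\\s*(.*?)\\s*</script>.*',
              "\\1", html)
  b2 <- bundleFromJSON(json)
  expect_identical(modeLabels(b2), modeLabels(b))
  expect_identical(popLabels(b2), popLabels(b))
  expect_equal(alignmentEdges(b2)$cost, alignmentEdges(b)$cost)
  for (i in seq_along(bundleModes(b)))
    expect_equal(qMatrix(bundleModes(b2)[[i]]), qMatrix(bundleModes(b)[[i]]),
                 tolerance = 1e-12)
})
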