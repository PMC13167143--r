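## Deterministic SVG rendering of the multipartite grid of structure
## plots, the separate vertical cluster legend, PNG export (same-geometry
## redraw on a raster device), and a self-contained interactive HTML
## export. All numeric attributes are emitted at fixed precision so that
## identical (bundle, state) inputs give byte-identical SVG.

DIM_OPACITY <- 0.25  # opacity of non-highlighted segments

fmtU <- function(x) sprintf("%.2f", x)

svgEsc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub('"', "&quot;", x, fixed = TRUE)
  x
}

emptyScene <- function() {
  data.frame(kind = character(0), x = numeric(0), y = numeric(0),
             w = numeric(0), h = numeric(0), x2 = numeric(0), y2 = numeric(0),
             fill = character(0), opacity = numeric(0), text = character(0),
             size = numeric(0), angle = numeric(0), anchor = character(0),
             lwd = numeric(0), stringsAsFactors = FALSE)
}

sceneRow <- function(kind, x = 0, y = 0, w = 0, h = 0, x2 = 0, y2 = 0,
                     fill = "#000000", opacity = 1, text = "", size = 10,
                     angle = 0, anchor = "middle", lwd = 1) {
  data.frame(kind = kind, x = x, y = y, w = w, h = h, x2 = x2, y2 = y2,
             fill = fill, opacity = opacity, text = text, size = size,
             angle = angle, anchor = anchor, lwd = lwd,
             stringsAsFactors = FALSE)
}

# tooltip without requiring the full bundle (mirrors tooltipText())
barTooltip <- function(mode, ind, labels, state) {
  q <- mode@Q[ind, ]
  head <- if (length(labels)) sprintf("Individual %d (%s)", ind, labels[ind])
          else sprintf("Individual %d", ind)
  stack <- rev(state@clusterStack)
  stack <- stack[stack <= mode@k]
  paste(c(head, sprintf("%s: %.3f", state@clusterNames[stack], q[stack])),
        collapse = "\n")
}

# one structure plot: bars, population separators, x-axis labels
structurePlotPiece <- function(mode, state, x, y, width, height,
                               labels = character(0)) {
  if (width <= 0 || height <= 0)
    avValueError("plot geometry must have positive width and height")
  ord <- effectiveOrder(labels, state@indOrder, state@popOrder)
  n <- length(ord)
  barw <- width / n
  stack <- state@clusterStack[state@clusterStack <= mode@k]
  hl <- state@highlight

  svg <- sprintf('<g class="structure-plot" data-mode="%s">', svgEsc(mode@label))
  scene <- vector("list", n + 8L)
  si <- 0L
  for (p in seq_len(n)) {
    i <- ord[p]
    bx <- x + (p - 1) * barw
    cum <- 0
    rects <- character(length(stack))
    srect <- matrix(0, length(stack), 3)  # y, h, opacity
    for (j in seq_along(stack)) {
      cl <- stack[j]
      hseg <- mode@Q[i, cl] * height
      ry <- y + height - cum - hseg
      op <- if (!is.na(hl) && cl != hl) DIM_OPACITY else 1
      rects[j] <- sprintf(
        '<rect x="%s" y="%s" width="%s" height="%s" fill="%s" fill-opacity="%s" data-mode="%s" data-ind="%d" data-cluster="%d"/>',
        fmtU(bx), fmtU(ry), fmtU(barw), fmtU(hseg), state@palette[cl],
        fmtU(op), svgEsc(mode@label), i, cl)
      srect[j, ] <- c(ry, hseg, op)
      cum <- cum + hseg
    }
    tip <- svgEsc(barTooltip(mode, i, labels, state))
    svg <- c(svg,
             sprintf('<g class="bar" data-mode="%s" data-ind="%d"><title>%s</title>%s</g>',
                     svgEsc(mode@label), i, tip, paste(rects, collapse = "")))
    si <- si + 1L
    scene[[si]] <- sceneRow("rect", x = bx, y = srect[, 1], w = barw,
                            h = srect[, 2], fill = state@palette[stack],
                            opacity = srect[, 3])
  }

  # population blocks: separators between blocks, label at block midpoint
  if (length(labels)) {
    blab <- labels[ord]
    pops <- state@popOrder[state@popOrder %in% blab]
    sizes <- vapply(pops, function(p) sum(blab == p), integer(1))
    ends <- cumsum(sizes)
    starts <- c(0L, ends[-length(ends)])
    if (length(pops) > 1L) {
      for (e in ends[-length(ends)]) {
        sx <- x + e * barw
        svg <- c(svg, sprintf(
          '<line class="pop-separator" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#FFFFFF" stroke-width="0.8"/>',
          fmtU(sx), fmtU(y), fmtU(sx), fmtU(y + height)))
        si <- si + 1L
        scene[[si]] <- sceneRow("line", x = sx, y = y, x2 = sx, y2 = y + height,
                                fill = "#FFFFFF", lwd = 0.8)
      }
    }
    for (b in seq_along(pops)) {
      cx <- x + (starts[b] + sizes[b] / 2) * barw
      ly <- y + height + 12
      blockw <- sizes[b] * barw
      rot <- blockw < 6 * nchar(pops[b]) + 4  # rotate when the block is narrow
      if (rot) {
        svg <- c(svg, sprintf(
          '<text class="pop-label" x="%s" y="%s" font-size="10" text-anchor="start" transform="rotate(45 %s %s)">%s</text>',
          fmtU(cx), fmtU(ly), fmtU(cx), fmtU(ly), svgEsc(pops[b])))
        si <- si + 1L
        scene[[si]] <- sceneRow("text", x = cx, y = ly, text = pops[b],
                                size = 10, angle = 45, anchor = "start")
      } else {
        svg <- c(svg, sprintf(
          '<text class="pop-label" x="%s" y="%s" font-size="10" text-anchor="middle">%s</text>',
          fmtU(cx), fmtU(ly), svgEsc(pops[b])))
        si <- si + 1L
        scene[[si]] <- sceneRow("text", x = cx, y = ly, text = pops[b],
                                size = 10, angle = 0, anchor = "middle")
      }
    }
  }
  svg <- c(svg, "</g>")
  list(svg = paste(svg, collapse = "\n"),
       scene = do.call(rbind, scene[seq_len(si)]))
}

#' Render a single structure plot as an SVG fragment
#'
#' Draws one stacked bar per individual (in the state's individual
#' order, grouped into contiguous population blocks following the
#' population order), segments stacked bottom-up along the cluster
#' stack restricted to this mode's k, segment heights proportional to
#' membership so each bar fills the cell height exactly. Population
#' separators and x-axis labels are drawn when labels are supplied;
#' highlight dimming is applied; every bar embeds its tooltip as an SVG
#' `<title>` and every segment carries `data-mode`/`data-ind`/
#' `data-cluster` annotations.
#'
#' @param mode a [Mode-class].
#' @param state a [ViewState-class].
#' @param x,y cell origin in user units.
#' @param width,height cell size in user units (must be positive).
#' @param labels optional per-individual population labels.
#' @return a character scalar holding an SVG `<g>` fragment.
#' @export
renderStructurePlot <- function(mode, state, x = 0, y = 0,
                                width = 240, height = 80,
                                labels = character(0)) {
  stopifnot(is(mode, "Mode"), is(state, "ViewState"))
  structurePlotPiece(mode, state, x, y, width, height, labels)$svg
}

legendPiece <- function(state) {
  order <- rev(state@clusterStack)  # stacking order, top of plot first
  sw <- 18; gap <- 8; pad <- 10
  textw <- max(nchar(state@clusterNames)) * 7 + 10
  w <- pad * 2 + sw + 8 + textw
  h <- pad * 2 + length(order) * (sw + gap) - gap
  svg <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
    fmtU(w), fmtU(h), fmtU(w), fmtU(h)))
  scene <- vector("list", length(order) * 2L)
  si <- 0L
  for (j in seq_along(order)) {
    cl <- order[j]
    ey <- pad + (j - 1) * (sw + gap)
    nm <- svgEsc(state@clusterNames[cl])
    svg <- c(svg, sprintf(
      '<g class="legend-entry" data-cluster="%d"><title>%s</title><rect x="%s" y="%s" width="%s" height="%s" fill="%s"/><text x="%s" y="%s" font-size="12">%s</text></g>',
      cl, nm, fmtU(pad), fmtU(ey), fmtU(sw), fmtU(sw), state@palette[cl],
      fmtU(pad + sw + 8), fmtU(ey + sw - 5), nm))
    si <- si + 1L
    scene[[si]] <- sceneRow("rect", x = pad, y = ey, w = sw, h = sw,
                            fill = state@palette[cl])
    si <- si + 1L
    scene[[si]] <- sceneRow("text", x = pad + sw + 8, y = ey + sw - 5,
                            text = state@clusterNames[cl], size = 12,
                            anchor = "start")
  }
  svg <- c(svg, "</svg>")
  list(svg = paste0(paste(svg, collapse = "\n"), "\n"),
       scene = do.call(rbind, scene[seq_len(si)]),
       width = w, height = h)
}

#' Render the full figure
#'
#' Composes the grid layout, one structure plot per visible mode (all
#' modes, or major modes only when the state hides minor modes),
#' alignment edges with cost-mapped darkness (when shown and available),
#' per-mode text labels of the form `"K={k} {label} ({runs} runs)"`
#' (when shown), and the separate vertical cluster legend document.
#' Output is deterministic: identical (bundle, state) inputs give
#' byte-identical SVG.
#'
#' @param bundle a [ModeBundle-class].
#' @param state a [ViewState-class].
#' @param plotWidth structure-plot width in user units; default
#'   `max(N, 240)` (one unit per individual, with a floor for legibility).
#' @param plotHeight structure-plot height (default 80).
#' @param hgap,vgap gaps between grid cells (defaults 40 and 60).
#' @return a [RenderedFigure-class].
#' @export
renderFigure <- function(bundle, state, plotWidth = NULL, plotHeight = 80,
                         hgap = 40, vgap = 60) {
  stopifnot(is(bundle, "ModeBundle"), is(state, "ViewState"))
  modes <- visibleModes(bundle, state)
  if (!length(modes)) avValueError("no modes to render")
  if (is.null(plotWidth)) plotWidth <- max(bundle@nInd, 240)
  layout <- layoutGrid(modes, plotWidth, plotHeight, hgap, vgap,
                       edges = if (state@showEdges) bundle@edges else NULL)
  xoff <- 20; yoff <- 30; bottom <- 70; right <- 20
  cells <- layout@cells
  W <- max(cells$x + cells$width) + xoff + right
  H <- max(cells$y + cells$height) + yoff + bottom
  labels <- if (hasPopLabels(bundle)) bundle@labels else character(0)

  parts <- character(0)
  scenes <- list()

  if (state@showEdges) {
    edgeSvg <- character(0)
    segs <- layout@edgeSegments
    if (nrow(segs)) {
      for (e in seq_len(nrow(segs))) {
        tip <- svgEsc(edgeTooltipText(segs$modeA[e], segs$modeB[e], segs$cost[e]))
        edgeSvg <- c(edgeSvg, sprintf(
          '<g class="alignment-edge" data-a="%s" data-b="%s"><title>%s</title><line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#000000" stroke-opacity="%s" stroke-width="2"/></g>',
          svgEsc(segs$modeA[e]), svgEsc(segs$modeB[e]), tip,
          fmtU(segs$x1[e] + xoff), fmtU(segs$y1[e] + yoff),
          fmtU(segs$x2[e] + xoff), fmtU(segs$y2[e] + yoff),
          fmtU(segs$opacity[e])))
      }
      scenes[[length(scenes) + 1L]] <-
        sceneRow("line", x = segs$x1 + xoff, y = segs$y1 + yoff,
                 x2 = segs$x2 + xoff, y2 = segs$y2 + yoff,
                 fill = "#000000", opacity = segs$opacity, lwd = 2)
    }
    parts <- c(parts, '<g class="edges">', edgeSvg, "</g>")
  }

  for (i in seq_along(modes)) {
    m <- modes[[i]]
    cell <- cells[cells$label == m@label, ]
    piece <- structurePlotPiece(m, state, cell$x + xoff, cell$y + yoff,
                                cell$width, cell$height, labels)
    parts <- c(parts, piece$svg)
    scenes[[length(scenes) + 1L]] <- piece$scene
    if (state@showModeLabels) {
      txt <- sprintf("K=%d %s (%d runs)", m@k, m@label, m@runs)
      parts <- c(parts, sprintf(
        '<text class="mode-label" x="%s" y="%s" font-size="11" text-anchor="start">%s</text>',
        fmtU(cell$x + xoff), fmtU(cell$y + yoff - 6), svgEsc(txt)))
      scenes[[length(scenes) + 1L]] <-
        sceneRow("text", x = cell$x + xoff, y = cell$y + yoff - 6,
                 text = txt, size = 11, anchor = "start")
    }
  }

  svg <- paste0(paste(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
            fmtU(W), fmtU(H), fmtU(W), fmtU(H)),
    parts, "</svg>"), collapse = "\n"), "\n")

  leg <- legendPiece(state)
  scene <- if (length(scenes)) do.call(rbind, scenes) else emptyScene()
  new("RenderedFigure", svg = svg, width = W, height = H,
      legendSvg = leg$svg, scene = scene, legendScene = leg$scene)
}

# redraw a scene (the exact geometry serialized into the SVG) on a
# cairo png device
rasterScene <- function(scene, width, height, dpi, path) {
  scale <- dpi / 96
  grDevices::png(path, width = max(1, round(width * scale)),
                 height = max(1, round(height * scale)),
                 res = dpi, bg = "white", type = "cairo")
  on.exit(grDevices::dev.off(), add = TRUE)
  grid::grid.newpage()
  grid::pushViewport(grid::viewport(
    xscale = c(0, width), yscale = c(0, height),
    width = grid::unit(1, "npc"), height = grid::unit(1, "npc")))
  flipY <- function(y) height - y
  for (i in seq_len(nrow(scene))) {
    s <- scene[i, ]
    if (s$kind == "rect" && s$h > 0 && s$w > 0) {
      grid::grid.rect(
        x = grid::unit(s$x + s$w / 2, "native"),
        y = grid::unit(flipY(s$y + s$h / 2), "native"),
        width = grid::unit(s$w, "native"), height = grid::unit(s$h, "native"),
        gp = grid::gpar(fill = grDevices::adjustcolor(s$fill, alpha.f = s$opacity),
                        col = NA))
    } else if (s$kind == "line") {
      grid::grid.segments(
        x0 = grid::unit(s$x, "native"), y0 = grid::unit(flipY(s$y), "native"),
        x1 = grid::unit(s$x2, "native"), y1 = grid::unit(flipY(s$y2), "native"),
        gp = grid::gpar(col = grDevices::adjustcolor(s$fill, alpha.f = s$opacity),
                        lwd = s$lwd))
    } else if (s$kind == "text") {
      grid::grid.text(
        s$text, x = grid::unit(s$x, "native"),
        y = grid::unit(flipY(s$y), "native"),
        just = if (s$anchor == "start") c("left", "bottom") else c("centre", "bottom"),
        rot = -s$angle,
        gp = grid::gpar(fontsize = s$size, col = "#000000"))
    }
  }
  invisible(path)
}

#' Export a rendered figure
#'
#' Writes three files: `{prefix}.svg` (the graph view), `{prefix}.png`
#' (a rasterization of the same geometry at `dpi`), and
#' `{prefix}_legend.png` (the cluster legend). The export always
#' renders from the figure as given, so any view-state customization
#' already applied is maintained. Re-exporting the same figure writes a
#' byte-identical SVG.
#'
#' @param figure a [RenderedFigure-class] from [renderFigure()].
#' @param outPrefix output path prefix (directory must exist).
#' @param dpi raster resolution (default 200).
#' @return invisibly, a named character vector of the three paths.
#' @export
exportFigure <- function(figure, outPrefix, dpi = 200) {
  stopifnot(is(figure, "RenderedFigure"))
  dir <- dirname(outPrefix)
  if (!dir.exists(dir))
    avExportError("export failed at stage 'svg-write': directory %s does not exist", dir)
  svgPath <- paste0(outPrefix, ".svg")
  pngPath <- paste0(outPrefix, ".png")
  legPath <- paste0(outPrefix, "_legend.png")
  ok <- tryCatch({ cat(figure@svg, file = svgPath); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) avExportError("export failed at stage 'svg-write': cannot write %s", svgPath)
  tryCatch(rasterScene(figure@scene, figure@width, figure@height, dpi, pngPath),
           error = function(e)
             avExportError("export failed at stage 'png-rasterization': %s",
                           conditionMessage(e)))
  ls <- figure@legendScene
  lw <- max(ls$x + ls$w + ifelse(ls$kind == "text", nchar(ls$text) * 7, 0)) + 10
  lh <- max(ls$y + ls$h) + 10
  tryCatch(rasterScene(figure@legendScene, lw, lh, dpi, legPath),
           error = function(e)
             avExportError("export failed at stage 'legend-rasterization': %s",
                           conditionMessage(e)))
  invisible(c(svg = svgPath, png = pngPath, legend_png = legPath))
}

#' Serialize a bundle to JSON
#'
#' Full-precision JSON holding every mode's matrix, labels, edges and
#' run counts; [bundleFromJSON()] restores an equal bundle. Used by the
#' interactive HTML export to embed the data.
#'
#' @param bundle a [ModeBundle-class].
#' @return a JSON string.
#' @export
bundleToJSON <- function(bundle) {
  stopifnot(is(bundle, "ModeBundle"))
  obj <- list(
    n_individuals = bundle@nInd,
    labels = bundle@labels,
    edges = bundle@edges,
    modes = lapply(bundle@modes, function(m)
      list(label = m@label, k = m@k, rank = m@rank, runs = m@runs, q = m@Q))
  )
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
}

#' Restore a bundle from JSON
#'
#' @param x a JSON string (or file path) from [bundleToJSON()].
#' @return a [ModeBundle-class].
#' @export
bundleFromJSON <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyDataFrame = TRUE, simplifyMatrix = TRUE)
  modes <- lapply(seq_along(obj$modes$label), function(i)
    Mode(obj$modes$k[i], obj$modes$rank[i], obj$modes$runs[i],
         obj$modes$q[[i]]))
  edges <- if (is.null(obj$edges) || !length(obj$edges)) NULL
           else as.data.frame(obj$edges)
  ModeBundle(modes, labels = as.character(obj$labels), edges = edges)
}

#' Export a self-contained interactive HTML document
#'
#' Writes a single HTML file embedding the bundle data as JSON, the
#' rendered SVG, and a small script implementing highlight-on-hover
#' over the legend plus show/hide toggles for alignment edges and mode
#' labels. The document references no external resources and opens
#' offline in a browser.
#'
#' @param bundle a [ModeBundle-class].
#' @param state a [ViewState-class].
#' @param outPath output file path.
#' @param ... geometry arguments forwarded to [renderFigure()].
#' @return invisibly, `outPath`.
#' @export
exportInteractiveHTML <- function(bundle, state, outPath, ...) {
  fig <- renderFigure(bundle, state, ...)
  leg <- legendPiece(state)
  json <- bundleToJSON(bundle)
  html <- paste(c(
    "<!DOCTYPE html>",
    '<html lang="en"><head><meta charset="utf-8"/>',
    "<title>Aligned clustering modes</title>",
    "<style>body{font-family:sans-serif;margin:16px}#controls{margin-bottom:8px}",
    ".legend-entry{cursor:pointer}#wrap{display:flex;gap:24px}</style>",
    "</head><body>",
    '<div id="controls">',
    '<label><input type="checkbox" id="toggle-edges" checked/> alignment edges</label>',
    '<label><input type="checkbox" id="toggle-labels" checked/> mode labels</label>',
    "</div>",
    '<div id="wrap"><div id="legend">', leg$svg, "</div>",
    '<div id="figure">', fig@svg, "</div></div>",
    '<script type="application/json" id="bundle-data">', json, "</script>",
    "<script>",
    "var data=JSON.parse(document.getElementById('bundle-data').textContent);",
    "function setDisplay(sel,on){document.querySelectorAll(sel).forEach(function(e){e.style.display=on?'':'none';});}",
    "document.getElementById('toggle-edges').addEventListener('change',function(){setDisplay('.edges',this.checked);});",
    "document.getElementById('toggle-labels').addEventListener('change',function(){setDisplay('.mode-label',this.checked);});",
    "document.querySelectorAll('.legend-entry').forEach(function(le){",
    " var cl=le.getAttribute('data-cluster');",
    " le.addEventListener('mouseenter',function(){document.querySelectorAll('#figure rect[data-cluster]').forEach(function(r){r.setAttribute('fill-opacity',r.getAttribute('data-cluster')===cl?'1.00':'0.25');});});",
    " le.addEventListener('mouseleave',function(){document.querySelectorAll('#figure rect[data-cluster]').forEach(function(r){r.setAttribute('fill-opacity','1.00');});});",
    "});",
    "</script></body></html>"), collapse = "\n")
  ok <- tryCatch({ writeLines(html, outPath); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) avIOError("cannot write HTML to %s", outPath)
  invisible(outPath)
}
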