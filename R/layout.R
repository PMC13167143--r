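## Grid placement of modes (rows = K ascending, columns = mode rank) and
## alignment-edge geometry with the cost -> darkness mapping.

#' Map an alignment cost to an edge opacity
#'
#' Linear map over the observed cost range: the best (lowest) cost is
#' drawn darkest (opacity 1.0) and the worst (highest) cost faintest
#' (opacity 0.15 — a floor so the worst edge remains visible). A
#' degenerate range (`costMin == costMax`) maps to 1.0. Costs outside
#' the range are clamped with a warning.
#'
#' @param cost numeric cost(s).
#' @param costMin,costMax the cost range observed across drawn edges.
#' @return opacity values in \[0.15, 1\].
#' @examples
#' edgeOpacity(c(0, 0.5, 1), 0, 1)
#' @export
edgeOpacity <- function(cost, costMin, costMax) {
  if (costMax < costMin) avValueError("costMax must be >= costMin")
  if (any(cost < costMin) || any(cost > costMax)) {
    warning("alignment cost outside [costMin, costMax]; clamping", call. = FALSE)
    cost <- pmin(pmax(cost, costMin), costMax)
  }
  if (costMax == costMin) return(rep(1.0, length(cost)))
  1.0 + (0.15 - 1.0) * (cost - costMin) / (costMax - costMin)
}

#' Select the alignment edges to draw
#'
#' Keeps only edges whose both endpoints are in the visible mode list
#' and whose K values differ by exactly 1 (the display connects modes
#' across adjacent K only; Clumppling can report all pairs). Dropped
#' edges are counted in a message.
#'
#' @param edges data.frame of edges (`modeA`, `modeB`, `cost`).
#' @param modes list of visible [Mode-class] objects.
#' @return the retained subset of `edges`, in input order.
#' @export
selectEdges <- function(edges, modes) {
  if (is.null(edges) || !nrow(edges)) return(emptyEdges())
  labs <- vapply(modes, function(m) m@label, character(1))
  ks <- stats::setNames(vapply(modes, function(m) m@k, integer(1)), labs)
  vis <- edges$modeA %in% labs & edges$modeB %in% labs
  adj <- rep(FALSE, nrow(edges))
  adj[vis] <- abs(ks[edges$modeA[vis]] - ks[edges$modeB[vis]]) == 1L
  keep <- vis & adj
  if (any(!keep))
    message(sprintf("dropping %d alignment edge(s) (hidden endpoint or non-adjacent K)",
                    sum(!keep)))
  edges[keep, , drop = FALSE]
}

#' Lay out modes on the K-by-mode grid
#'
#' Rows are K values in ascending order top-to-bottom; the column index
#' of a mode is its mode rank minus 1, so the major mode of the smallest
#' K occupies the upper-left cell. All plots are the same size; rows
#' with fewer modes are left-aligned. Coordinates are deterministic
#' functions of (K rank, mode rank) only. When `edges` are supplied,
#' edge segments are computed for the adjacent-K edges among these
#' modes: each runs from the bottom-center of the upper (smaller K) cell
#' to the top-center of the lower cell, offset horizontally by the
#' partner's column so parallel edges do not overlap, with opacity from
#' [edgeOpacity()] over the selected edges' cost range.
#'
#' @param modes list of [Mode-class] objects to place.
#' @param plotWidth,plotHeight cell size in abstract canvas units.
#' @param hgap,vgap horizontal / vertical gap between cells.
#' @param edges optional data.frame of alignment edges.
#' @return a [GridLayout-class].
#' @export
layoutGrid <- function(modes, plotWidth = 240, plotHeight = 80,
                       hgap = 40, vgap = 60, edges = NULL) {
  if (!length(modes)) avValueError("cannot lay out an empty mode list")
  ks <- vapply(modes, function(m) m@k, integer(1))
  rk <- vapply(modes, function(m) m@rank, integer(1))
  kvals <- sort(unique(ks))
  row <- match(ks, kvals)
  col <- rk
  cells <- data.frame(
    label = vapply(modes, function(m) m@label, character(1)),
    row = row, col = col,
    x = (col - 1) * (plotWidth + hgap),
    y = (row - 1) * (plotHeight + vgap),
    width = plotWidth, height = plotHeight,
    stringsAsFactors = FALSE)
  cells <- cells[order(cells$row, cells$col), , drop = FALSE]
  rownames(cells) <- NULL

  segs <- data.frame(modeA = character(0), modeB = character(0),
                     cost = numeric(0), x1 = numeric(0), y1 = numeric(0),
                     x2 = numeric(0), y2 = numeric(0), opacity = numeric(0),
                     stringsAsFactors = FALSE)
  if (!is.null(edges) && nrow(edges)) {
    sel <- selectEdges(edges, modes)
    if (nrow(sel)) {
      op <- edgeOpacity(sel$cost, min(sel$cost), max(sel$cost))
      ci <- match(sel$modeA, cells$label)
      cj <- match(sel$modeB, cells$label)
      # orient: upper = smaller y (smaller K)
      swap <- cells$y[ci] > cells$y[cj]
      tmp <- ci[swap]; ci[swap] <- cj[swap]; cj[swap] <- tmp
      off <- 8  # per-column horizontal fan-out of parallel edges
      segs <- data.frame(
        modeA = sel$modeA, modeB = sel$modeB, cost = sel$cost,
        x1 = cells$x[ci] + cells$width[ci] / 2 + (cells$col[cj] - 1) * off,
        y1 = cells$y[ci] + cells$height[ci],
        x2 = cells$x[cj] + cells$width[cj] / 2 + (cells$col[ci] - 1) * off,
        y2 = cells$y[cj],
        opacity = op, stringsAsFactors = FALSE)
    }
  }
  new("GridLayout", cells = cells, kValues = as.integer(kvals),
      edgeSegments = segs)
}
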