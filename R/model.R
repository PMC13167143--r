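## Mode labelling, bundle summaries, the default view state and its JSON
## (de)serialization, and the default colorblind-safe palette.

# Fixed 12-color colorblind-safe qualitative cycle (Paul Tol's "safe"
# qualitative scheme). Fixing the palette makes renders reproducible.
.AV_PALETTE <- c(
  "#88CCEE", "#CC6677", "#DDCC77", "#117733", "#332288", "#AA4499",
  "#44AA99", "#999933", "#882255", "#661100", "#6699CC", "#888888"
)

lightenHex <- function(hex, f = 0.45) {
  rgb <- grDevices::col2rgb(hex)
  rgb <- round(rgb + (255 - rgb) * f)
  toupper(grDevices::rgb(rgb[1, ], rgb[2, ], rgb[3, ], maxColorValue = 255))
}

#' Default cluster palette
#'
#' A fixed 12-color colorblind-safe qualitative cycle. For more than 12
#' clusters the cycle repeats with a lightened variant of each color and
#' a warning, so that renders remain deterministic.
#'
#' @param k number of clusters to color.
#' @return character vector of `k` hex colors.
#' @export
defaultPalette <- function(k) {
  base <- length(.AV_PALETTE)
  if (k <= base) return(.AV_PALETTE[seq_len(k)])
  warning(sprintf(
    "%d clusters exceed the %d-color palette; repeating with lightened variants",
    k, base), call. = FALSE)
  ext <- .AV_PALETTE
  while (length(ext) < k) ext <- c(ext, lightenHex(ext[seq_len(base)]))
  ext[seq_len(k)]
}

#' Assign mode labels from per-K run counts
#'
#' Within each K, modes are ranked by run count in descending order with
#' ties broken by input order (stable), and labelled `"K{k}M{rank}"`:
#' M1 is the mode with the most clustering runs, M2 the second most,
#' and so on.
#'
#' @param groups named list mapping K (names) to an integer vector of
#'   run counts, one per mode, in input order.
#' @return data.frame with columns `k`, `inputIndex` (position within
#'   the K group as supplied), `rank`, `runs`, `label`.
#' @examples
#' assignModeLabels(list(`3` = c(5, 2, 1)))
#' @export
assignModeLabels <- function(groups) {
  if (!length(groups) || is.null(names(groups)))
    avValueError("groups must be a named list mapping K to run counts")
  out <- lapply(names(groups), function(kname) {
    counts <- as.integer(groups[[kname]])
    k <- as.integer(kname)
    if (!length(counts)) avValueError("empty mode group for K=%d", k)
    if (any(counts < 1L)) avValueError("run counts must be >= 1 (K=%d)", k)
    ord <- order(-counts, seq_along(counts))  # stable: ties keep input order
    data.frame(k = k, inputIndex = ord, rank = seq_along(counts),
               runs = counts[ord],
               label = sprintf("K%dM%d", k, seq_along(counts)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[order(res$k, res$rank), , drop = FALSE]
}

#' Summarize a mode bundle
#'
#' @param bundle a [ModeBundle-class].
#' @return list with `n_individuals`, `n_populations` (0 when no labels
#'   were provided), `n_modes`, `k_values` (ascending), and `total_runs`
#'   (sum of run counts over all modes).
#' @export
summarizeBundle <- function(bundle) {
  stopifnot(is(bundle, "ModeBundle"))
  list(
    n_individuals = bundle@nInd,
    n_populations = if (length(bundle@labels)) length(unique(bundle@labels)) else 0L,
    n_modes = length(bundle@modes),
    k_values = kValues(bundle),
    total_runs = sum(vapply(bundle@modes, function(m) m@runs, integer(1)))
  )
}

#' Default view state for a bundle
#'
#' Identity orderings for clusters and individuals, populations in order
#' of first appearance, the default colorblind-safe palette, no
#' highlight, and all display toggles on (edges and mode labels shown,
#' minor modes shown).
#'
#' @param bundle a [ModeBundle-class].
#' @return a [ViewState-class].
#' @export
defaultView <- function(bundle) {
  stopifnot(is(bundle, "ModeBundle"))
  kmax <- bundleKmax(bundle)
  new("ViewState",
      clusterStack = seq_len(kmax),
      popOrder = unique(popLabels(bundle)),
      indOrder = seq_len(bundle@nInd),
      palette = defaultPalette(kmax),
      highlight = NA_integer_,
      showEdges = TRUE, showModeLabels = TRUE, hideMinorModes = FALSE,
      clusterNames = sprintf("Cluster %d", seq_len(kmax)))
}

#' Serialize a view state to JSON
#'
#' The JSON form is stable and complete, so that a command-line run can
#' be replayed exactly: restoring the state and re-rendering reproduces
#' the figure byte for byte.
#'
#' @param state a [ViewState-class].
#' @param path optional file to write; when `NULL` the JSON text is
#'   returned.
#' @return JSON text (invisibly when written to `path`).
#' @export
viewStateToJSON <- function(state, path = NULL) {
  stopifnot(is(state, "ViewState"))
  obj <- list(
    cluster_stack_order = state@clusterStack,
    population_order = state@popOrder,
    individual_order = state@indOrder,
    palette = state@palette,
    highlight = if (is.na(state@highlight)) NULL else state@highlight,
    show_edges = state@showEdges,
    show_mode_labels = state@showModeLabels,
    hide_minor_modes = state@hideMinorModes,
    cluster_names = state@clusterNames
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Restore a view state from JSON
#'
#' @param x a file path or a JSON string produced by [viewStateToJSON()].
#' @return a [ViewState-class].
#' @export
viewStateFromJSON <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyVector = TRUE)
  hl <- if (is.null(obj$highlight)) NA_integer_ else as.integer(obj$highlight)
  new("ViewState",
      clusterStack = as.integer(obj$cluster_stack_order),
      popOrder = as.character(obj$population_order),
      indOrder = as.integer(obj$individual_order),
      palette = as.character(obj$palette),
      highlight = hl,
      showEdges = isTRUE(obj$show_edges),
      showModeLabels = isTRUE(obj$show_mode_labels),
      hideMinorModes = isTRUE(obj$hide_minor_modes),
      clusterNames = as.character(obj$cluster_names))
}
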