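#' @import methods
NULL

# Classed conditions so callers (and the CLI) can map failures to exit codes.
avStop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "admixviewError", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

avFormatError  <- function(msg, ...) avStop("avFormatError", msg, ...)
avValueError   <- function(msg, ...) avStop("avValueError", msg, ...)
avLookupError  <- function(msg, ...) avStop("avLookupError", msg, ...)
avIOError      <- function(msg, ...) avStop("avIOError", msg, ...)
avExportError  <- function(msg, ...) avStop("avExportError", msg, ...)
avFeatureDisabledError <- function(msg, ...) avStop("avFeatureDisabledError", msg, ...)

#' Validate a membership (Q) matrix
#'
#' A membership matrix holds, for each of N individuals, the estimated
#' proportions of their genome derived from each of K latent ancestry
#' clusters. Valid matrices are numeric, have N >= 1 rows and K >= 1
#' columns, entries in \[0, 1\], and rows that sum to 1 within `tol`.
#'
#' @param values numeric matrix, N rows (individuals) by K columns (clusters).
#' @param tol numeric row-sum tolerance (default 1e-9).
#' @return `TRUE` invisibly; otherwise a classed error is signalled.
#' @export
validateQMatrix <- function(values, tol = 1e-9) {
  if (!is.matrix(values) || !is.numeric(values))
    avValueError("membership matrix must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    avValueError("membership matrix must have N >= 1 rows and K >= 1 columns")
  if (anyNA(values))
    avValueError("membership matrix contains missing values")
  if (any(values < 0) || any(values > 1))
    avValueError("membership coefficients must lie in [0, 1]")
  dev <- abs(rowSums(values) - 1)
  if (any(dev > tol))
    avValueError("row %d of membership matrix sums to %.9f, not 1",
                 which.max(dev), rowSums(values)[which.max(dev)])
  invisible(TRUE)
}

#' Mode: one aligned clustering solution
#'
#' A mode is a distinct clustering solution at a given K, to which one or
#' more clustering runs align. Modes are labelled `"K{k}M{rank}"`, where
#' rank 1 (the major mode) is the solution with the most runs.
#'
#' @slot label character, exactly `"K{k}M{rank}"`.
#' @slot k integer number of clusters.
#' @slot rank integer mode rank within its K (1 = major).
#' @slot runs integer number of clustering runs aligned to this mode.
#' @slot Q numeric membership matrix, N x k, rows summing to 1.
#' @export
setClass("Mode", representation(
  label = "character", k = "integer", rank = "integer",
  runs = "integer", Q = "matrix"
))

setValidity("Mode", function(object) {
  msgs <- character(0)
  if (length(object@k) != 1L || object@k < 1L) msgs <- c(msgs, "k must be a single integer >= 1")
  if (length(object@rank) != 1L || object@rank < 1L) msgs <- c(msgs, "rank must be a single integer >= 1")
  if (length(object@runs) != 1L || object@runs < 1L) msgs <- c(msgs, "runs must be a single integer >= 1")
  expected <- sprintf("K%dM%d", object@k, object@rank)
  if (!identical(object@label, expected))
    msgs <- c(msgs, sprintf("label must be '%s', got '%s'", expected, object@label))
  if (ncol(object@Q) != object@k)
    msgs <- c(msgs, sprintf("matrix has %d columns but k = %d", ncol(object@Q), object@k))
  v <- tryCatch({ validateQMatrix(object@Q); NULL }, error = function(e) conditionMessage(e))
  if (!is.null(v)) msgs <- c(msgs, v)
  if (length(msgs)) msgs else TRUE
})

#' Construct a Mode
#'
#' @param k integer number of clusters.
#' @param rank integer mode rank (1 = major mode).
#' @param runs integer run count (default 1).
#' @param Q numeric N x k membership matrix with rows summing to 1.
#' @return a [Mode-class] object.
#' @examples
#' m <- Mode(k = 2, rank = 1, runs = 3, Q = rbind(c(1, 0), c(0.4, 0.6)))
#' modeLabel(m)
#' @export
Mode <- function(k, rank = 1L, runs = 1L, Q) {
  new("Mode", label = sprintf("K%dM%d", as.integer(k), as.integer(rank)),
      k = as.integer(k), rank = as.integer(rank), runs = as.integer(runs),
      Q = as.matrix(Q))
}

#' ModeBundle: all aligned modes of one analysis
#'
#' Holds every clustering mode across all K values, with a shared set of
#' individuals, optional per-individual population labels, and optional
#' mode-pair alignment edges (lower cost = better alignment).
#'
#' @slot modes list of [Mode-class] objects, sorted by (K, rank).
#' @slot labels character of length N (population label per individual),
#'   or length 0 when no labels were provided.
#' @slot edges data.frame with columns `modeA`, `modeB`, `cost`.
#' @slot nInd integer number of individuals shared by every matrix.
#' @export
setClass("ModeBundle", representation(
  modes = "list", labels = "character", edges = "data.frame", nInd = "integer"
))

setValidity("ModeBundle", function(object) {
  msgs <- character(0)
  if (length(object@modes) < 1L) msgs <- c(msgs, "bundle must contain at least one mode")
  if (!all(vapply(object@modes, is, logical(1), "Mode")))
    msgs <- c(msgs, "all bundle entries must be Mode objects")
  else {
    ns <- vapply(object@modes, function(m) nrow(m@Q), integer(1))
    if (any(ns != object@nInd))
      msgs <- c(msgs, "all membership matrices must share the same number of individuals")
    labs <- vapply(object@modes, function(m) m@label, character(1))
    if (anyDuplicated(labs)) msgs <- c(msgs, "duplicate mode labels in bundle")
    ks <- vapply(object@modes, function(m) m@k, integer(1))
    for (k in unique(ks)) {
      grp <- object@modes[ks == k]
      rk <- vapply(grp, function(m) m@rank, integer(1))
      if (!setequal(rk, seq_along(grp)))
        msgs <- c(msgs, sprintf("mode ranks for K=%d are not 1..%d", k, length(grp)))
      rc <- vapply(grp, function(m) m@runs, integer(1))[order(rk)]
      if (is.unsorted(rev(rc), strictly = FALSE))
        msgs <- c(msgs, sprintf("run counts for K=%d are not non-increasing in mode rank", k))
    }
    if (length(object@labels) && length(object@labels) != object@nInd)
      msgs <- c(msgs, "population labels must have one entry per individual")
    if (nrow(object@edges)) {
      if (!all(c("modeA", "modeB", "cost") %in% names(object@edges)))
        msgs <- c(msgs, "edges must have columns modeA, modeB, cost")
      else {
        if (any(object@edges$cost < 0)) msgs <- c(msgs, "alignment costs must be >= 0")
        ep <- c(object@edges$modeA, object@edges$modeB)
        if (!all(ep %in% labs)) msgs <- c(msgs, "every edge endpoint must name a mode in the bundle")
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

emptyEdges <- function() {
  data.frame(modeA = character(0), modeB = character(0), cost = numeric(0),
             stringsAsFactors = FALSE)
}

#' Construct a ModeBundle
#'
#' Modes are sorted by (K, mode rank); edges and labels are optional.
#'
#' @param modes list of [Mode-class] objects.
#' @param labels optional character vector of population labels, one per
#'   individual in file order.
#' @param edges optional data.frame (`modeA`, `modeB`, `cost`) of
#'   alignment edges.
#' @return a [ModeBundle-class] object.
#' @export
ModeBundle <- function(modes, labels = character(0), edges = NULL) {
  if (length(modes) < 1L) avValueError("bundle must contain at least one mode")
  ks <- vapply(modes, function(m) m@k, integer(1))
  rk <- vapply(modes, function(m) m@rank, integer(1))
  modes <- modes[order(ks, rk)]
  if (is.null(edges)) edges <- emptyEdges()
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  new("ModeBundle", modes = modes, labels = as.character(labels),
      edges = edges, nInd = nrow(modes[[1]]@Q))
}

#' ViewState: the mutable display state of a figure
#'
#' Every interactive transform (reordering clusters or populations,
#' dominance sorting, highlighting, renaming, palette changes, display
#' toggles) acts on this state; rendering is a pure function of
#' (bundle, state).
#'
#' @slot clusterStack integer permutation of 1..Kmax, stored bottom-up:
#'   the first entry is drawn at the bottom of every structure plot.
#' @slot popOrder character permutation of the population names.
#' @slot indOrder integer permutation of 1..N.
#' @slot palette character vector of `#RRGGBB` colors, one per cluster index.
#' @slot highlight integer cluster index, or `NA` for no highlight.
#' @slot showEdges logical, draw alignment edges.
#' @slot showModeLabels logical, draw per-mode text labels.
#' @slot hideMinorModes logical, restrict display to major (rank 1) modes.
#' @slot clusterNames character display names, one per cluster index.
#' @export
setClass("ViewState", representation(
  clusterStack = "integer", popOrder = "character", indOrder = "integer",
  palette = "character", highlight = "integer", showEdges = "logical",
  showModeLabels = "logical", hideMinorModes = "logical",
  clusterNames = "character"
))

setValidity("ViewState", function(object) {
  msgs <- character(0)
  kmax <- length(object@clusterStack)
  if (!identical(sort(object@clusterStack), seq_len(kmax)))
    msgs <- c(msgs, "clusterStack must be a permutation of 1..Kmax")
  if (!identical(sort(object@indOrder), seq_along(object@indOrder)))
    msgs <- c(msgs, "indOrder must be a permutation of 1..N")
  if (anyDuplicated(object@popOrder)) msgs <- c(msgs, "popOrder must not contain duplicates")
  if (length(object@highlight) != 1L)
    msgs <- c(msgs, "highlight must be a single index or NA")
  else if (!is.na(object@highlight) &&
           (object@highlight < 1L || object@highlight > kmax))
    msgs <- c(msgs, "highlight must be a valid cluster index")
  if (length(object@palette) != kmax) msgs <- c(msgs, "palette must cover every cluster index")
  if (length(object@clusterNames) != kmax) msgs <- c(msgs, "clusterNames must cover every cluster index")
  if (length(msgs)) msgs else TRUE
})

#' GridLayout: mode placement on the K-by-mode grid
#'
#' Rows are K values ascending top-to-bottom; the column of a mode is its
#' mode rank, so the major mode of the smallest K occupies the upper-left
#' cell. Edge segments connect modes whose K values differ by exactly 1.
#'
#' @slot cells data.frame: `label`, `row`, `col`, `x`, `y`, `width`,
#'   `height` in abstract canvas units (mapped 1:1 to SVG user units).
#' @slot kValues integer K values, ascending, one per grid row.
#' @slot edgeSegments data.frame: `modeA`, `modeB`, `cost`, anchor
#'   coordinates `x1`,`y1`,`x2`,`y2`, and `opacity` in \[0.15, 1\].
#' @export
setClass("GridLayout", representation(
  cells = "data.frame", kValues = "integer", edgeSegments = "data.frame"
))

#' RenderedFigure: the final SVG documents
#'
#' @slot svg character scalar, the full SVG document of the graph view.
#' @slot width,height numeric canvas size in user units.
#' @slot legendSvg character scalar, the vertical cluster legend document.
#' @slot scene data.frame of drawing primitives (internal; used to redraw
#'   the identical geometry on a raster device for PNG export).
#' @slot legendScene data.frame of legend drawing primitives.
#' @export
setClass("RenderedFigure", representation(
  svg = "character", width = "numeric", height = "numeric",
  legendSvg = "character", scene = "data.frame", legendScene = "data.frame"
))

## ---- accessors -------------------------------------------------------------

#' Accessors for modes and bundles
#'
#' @param object a [Mode-class] or [ModeBundle-class].
#' @return `modeLabel`, `modeK`, `modeRank`, `runCount`, and `qMatrix`
#'   return the corresponding slot of a mode. `bundleModes` returns the
#'   list of modes, `nIndividuals` the shared individual count,
#'   `popLabels` the per-individual population labels (a single
#'   pseudo-population `"ALL"` when none were supplied), `hasPopLabels`
#'   whether real labels exist, `alignmentEdges` the edge data.frame,
#'   `modeLabels` all mode labels and `kValues` the distinct K values.
#' @name bundle-accessors
NULL

#' @rdname bundle-accessors
#' @export
setGeneric("modeLabel", function(object) standardGeneric("modeLabel"))
#' @rdname bundle-accessors
#' @export
setMethod("modeLabel", "Mode", function(object) object@label)

#' @rdname bundle-accessors
#' @export
setGeneric("modeK", function(object) standardGeneric("modeK"))
#' @rdname bundle-accessors
#' @export
setMethod("modeK", "Mode", function(object) object@k)

#' @rdname bundle-accessors
#' @export
setGeneric("modeRank", function(object) standardGeneric("modeRank"))
#' @rdname bundle-accessors
#' @export
setMethod("modeRank", "Mode", function(object) object@rank)

#' @rdname bundle-accessors
#' @export
setGeneric("runCount", function(object) standardGeneric("runCount"))
#' @rdname bundle-accessors
#' @export
setMethod("runCount", "Mode", function(object) object@runs)

#' @rdname bundle-accessors
#' @export
setGeneric("qMatrix", function(object) standardGeneric("qMatrix"))
#' @rdname bundle-accessors
#' @export
setMethod("qMatrix", "Mode", function(object) object@Q)

#' @rdname bundle-accessors
#' @export
setGeneric("bundleModes", function(object) standardGeneric("bundleModes"))
#' @rdname bundle-accessors
#' @export
setMethod("bundleModes", "ModeBundle", function(object) object@modes)

#' @rdname bundle-accessors
#' @export
setGeneric("nIndividuals", function(object) standardGeneric("nIndividuals"))
#' @rdname bundle-accessors
#' @export
setMethod("nIndividuals", "ModeBundle", function(object) object@nInd)

#' @rdname bundle-accessors
#' @export
setGeneric("hasPopLabels", function(object) standardGeneric("hasPopLabels"))
#' @rdname bundle-accessors
#' @export
setMethod("hasPopLabels", "ModeBundle", function(object) length(object@labels) > 0L)

#' @rdname bundle-accessors
#' @export
setGeneric("popLabels", function(object) standardGeneric("popLabels"))
#' @rdname bundle-accessors
#' @export
setMethod("popLabels", "ModeBundle", function(object) {
  if (length(object@labels)) object@labels else rep("ALL", object@nInd)
})

#' @rdname bundle-accessors
#' @export
setGeneric("alignmentEdges", function(object) standardGeneric("alignmentEdges"))
#' @rdname bundle-accessors
#' @export
setMethod("alignmentEdges", "ModeBundle", function(object) object@edges)

#' @rdname bundle-accessors
#' @export
setGeneric("modeLabels", function(object) standardGeneric("modeLabels"))
#' @rdname bundle-accessors
#' @export
setMethod("modeLabels", "ModeBundle", function(object)
  vapply(object@modes, function(m) m@label, character(1)))

#' @rdname bundle-accessors
#' @export
setGeneric("kValues", function(object) standardGeneric("kValues"))
#' @rdname bundle-accessors
#' @export
setMethod("kValues", "ModeBundle", function(object)
  sort(unique(vapply(object@modes, function(m) m@k, integer(1)))))

#' Look up a mode by label
#'
#' @param bundle a [ModeBundle-class].
#' @param label a mode label such as `"K5M1"`.
#' @return the matching [Mode-class]; a lookup error if absent.
#' @export
getMode <- function(bundle, label) {
  i <- match(label, modeLabels(bundle))
  if (is.na(i)) avLookupError("no mode labelled '%s' in bundle", label)
  bundle@modes[[i]]
}

# largest K in the bundle; drives palette and cluster-index space
bundleKmax <- function(bundle) max(vapply(bundle@modes, function(m) m@k, integer(1)))

#' @rdname bundle-accessors
#' @export
setGeneric("indOrder", function(object) standardGeneric("indOrder"))
#' @param object a [ViewState-class] for `indOrder`.
#' @rdname bundle-accessors
#' @export
setMethod("indOrder", "ViewState", function(object) object@indOrder)

setMethod("show", "Mode", function(object) {
  cat(sprintf("Mode %s: K=%d, rank %d, %d run%s, %d individuals\n",
              object@label, object@k, object@rank, object@runs,
              if (object@runs == 1L) "" else "s", nrow(object@Q)))
})

setMethod("show", "ModeBundle", function(object) {
  s <- summarizeBundle(object)
  cat(sprintf(
    "ModeBundle: %d modes over K = {%s}, %d individuals, %d population%s, %d total runs, %d alignment edge%s\n",
    s$n_modes, paste(s$k_values, collapse = ","), s$n_individuals,
    s$n_populations, if (s$n_populations == 1L) "" else "s",
    s$total_runs, nrow(object@edges), if (nrow(object@edges) == 1L) "" else "s"))
})

setMethod("show", "ViewState", function(object) {
  cat(sprintf(
    "ViewState: Kmax=%d, %d individuals, highlight=%s, edges=%s, mode labels=%s, minor modes %s\n",
    length(object@clusterStack), length(object@indOrder),
    if (is.na(object@highlight)) "none" else object@highlight,
    if (object@showEdges) "on" else "off",
    if (object@showModeLabels) "on" else "off",
    if (object@hideMinorModes) "hidden" else "shown"))
})
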