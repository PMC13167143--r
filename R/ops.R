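## The interactive-figure features as pure, deterministic transforms on
## (ModeBundle, ViewState): dominance sorting, population and cluster
## reordering, highlighting, minor-mode filtering, renaming, palette
## overrides, and tooltip text.

# Render-time individual order: individuals are always grouped into
# contiguous population blocks following popOrder, with within-block
# relative order taken from indOrder. Labels may be non-contiguous in
# file order; grouping is what makes x-axis blocks and separators possible.
effectiveOrder <- function(labels, indOrder, popOrder) {
  if (!length(labels)) return(indOrder)
  lab <- labels[indOrder]
  unlist(lapply(popOrder, function(p) indOrder[lab == p]), use.names = FALSE)
}

#' Sort individuals by cluster dominance
#'
#' For each population P (taken in the state's population order), the
#' dominant cluster d(P) is the cluster with the largest total
#' membership over the individuals of P in the chosen reference mode
#' (ties go to the lowest cluster index). Individuals within P are then
#' sorted by descending membership in d(P), ties broken by original
#' index (stable), and the blocks are concatenated in population order.
#' The resulting single ordering is installed in the state and thereby
#' applied to every mode at render time.
#'
#' The ordering depends only on the reference mode, the labels, and the
#' population order — not on the current individual order — so the
#' operation is idempotent.
#'
#' @param bundle a [ModeBundle-class].
#' @param referenceMode label of the mode whose memberships drive the sort.
#' @param state a [ViewState-class].
#' @return the updated [ViewState-class]; retrieve the permutation with
#'   [indOrder()].
#' @export
sortByClusterDominance <- function(bundle, referenceMode, state) {
  stopifnot(is(bundle, "ModeBundle"), is(state, "ViewState"))
  ref <- getMode(bundle, referenceMode)
  Q <- qMatrix(ref)
  labels <- popLabels(bundle)
  perm <- unlist(lapply(state@popOrder, function(p) {
    idx <- which(labels == p)
    if (!length(idx)) return(integer(0))
    tot <- colSums(Q[idx, , drop = FALSE])
    d <- which.max(tot)  # ties: lowest cluster index
    idx[order(-Q[idx, d], idx)]
  }), use.names = FALSE)
  state@indOrder <- as.integer(perm)
  validObject(state)
  state
}

#' Reorder populations
#'
#' Replaces the population order and rebuilds the individual order so
#' population blocks follow the new order while the relative order of
#' individuals within each block is preserved.
#'
#' @param bundle a [ModeBundle-class]; must carry population labels
#'   (the feature is disabled when none were provided).
#' @param state a [ViewState-class].
#' @param newOrder character permutation of the bundle's population names.
#' @return the updated [ViewState-class].
#' @export
reorderPopulations <- function(bundle, state, newOrder) {
  stopifnot(is(bundle, "ModeBundle"), is(state, "ViewState"))
  if (!hasPopLabels(bundle))
    avFeatureDisabledError("population reordering is disabled: no population labels were provided")
  cur <- state@popOrder
  newOrder <- as.character(newOrder)
  if (length(newOrder) != length(cur) || anyDuplicated(newOrder) ||
      !setequal(newOrder, cur))
    avValueError("new order must be a permutation of the population names: %s",
                 paste(cur, collapse = ", "))
  state@indOrder <- as.integer(effectiveOrder(popLabels(bundle),
                                              state@indOrder, newOrder))
  state@popOrder <- newOrder
  validObject(state)
  state
}

#' Reorder the cluster stack
#'
#' Takes the desired top-down order (the order shown in the vertical
#' legend: the first cluster appears at the bottom of the structure
#' plot, so the legend's top entry is drawn last). The state stores the
#' stack bottom-up. For a mode with k < Kmax the induced order is the
#' subsequence of the stack restricted to indices <= k. Per-individual
#' membership totals are unchanged.
#'
#' @param state a [ViewState-class].
#' @param topDownOrder integer permutation of 1..Kmax, top of plot first.
#' @return the updated [ViewState-class].
#' @export
reorderClusters <- function(state, topDownOrder) {
  stopifnot(is(state, "ViewState"))
  kmax <- length(state@clusterStack)
  topDownOrder <- as.integer(topDownOrder)
  if (length(topDownOrder) != kmax ||
      !identical(sort(topDownOrder), seq_len(kmax)))
    avValueError("cluster order must be a permutation of 1..%d", kmax)
  state@clusterStack <- rev(topDownOrder)
  state
}

#' Highlight a cluster
#'
#' Sets (or clears) the highlighted cluster. At render time the
#' highlighted cluster's segments are drawn at full opacity and all
#' other segments are dimmed to 25\% opacity, across all structure plots.
#'
#' @param state a [ViewState-class].
#' @param cluster cluster index to highlight, or `NULL`/`NA` to clear.
#' @return the updated [ViewState-class].
#' @export
highlightCluster <- function(state, cluster = NULL) {
  stopifnot(is(state, "ViewState"))
  kmax <- length(state@clusterStack)
  if (is.null(cluster) || (length(cluster) == 1L && is.na(cluster))) {
    state@highlight <- NA_integer_
    return(state)
  }
  cluster <- as.integer(cluster)
  if (length(cluster) != 1L || cluster < 1L || cluster > kmax)
    avValueError("highlight index must be in 1..%d", kmax)
  state@highlight <- cluster
  state
}

#' Keep only major modes
#'
#' Filters a bundle's mode list down to the major (rank 1) mode of each
#' K, in ascending K order. Idempotent. The corresponding display toggle
#' is the `hideMinorModes` flag of [ViewState-class], consumed by
#' [renderFigure()].
#'
#' @param bundle a [ModeBundle-class].
#' @return list of [Mode-class] objects with rank 1, K ascending.
#' @export
hideMinorModes <- function(bundle) {
  stopifnot(is(bundle, "ModeBundle"))
  keep <- Filter(function(m) m@rank == 1L, bundle@modes)
  keep[order(vapply(keep, function(m) m@k, integer(1)))]
}

# modes to draw under a given state, sorted by (K, rank)
visibleModes <- function(bundle, state) {
  ms <- if (state@hideMinorModes) hideMinorModes(bundle) else bundle@modes
  ks <- vapply(ms, function(m) m@k, integer(1))
  rk <- vapply(ms, function(m) m@rank, integer(1))
  ms[order(ks, rk)]
}

#' Rename clusters
#'
#' Updates cluster display names; legend entries and tooltips use the
#' new names. Clusters not mentioned keep their default name
#' `"Cluster {index}"` (or a previously assigned name).
#'
#' @param state a [ViewState-class].
#' @param names character vector of new names whose names are cluster
#'   indices, e.g. `c("1" = "African")`.
#' @return the updated [ViewState-class].
#' @export
renameClusters <- function(state, names) {
  stopifnot(is(state, "ViewState"))
  if (!length(names)) return(state)
  idx <- suppressWarnings(as.integer(base::names(names)))
  kmax <- length(state@clusterStack)
  if (anyNA(idx) || any(idx < 1L) || any(idx > kmax))
    avValueError("cluster name indices must be in 1..%d", kmax)
  state@clusterNames[idx] <- as.character(names)
  state
}

#' Override cluster colors
#'
#' @param state a [ViewState-class].
#' @param colors character vector of `#RRGGBB` colors whose names are
#'   cluster indices, e.g. `c("3" = "#FF0000")`. Unmentioned clusters
#'   keep their current color.
#' @return the updated [ViewState-class].
#' @export
setPalette <- function(state, colors) {
  stopifnot(is(state, "ViewState"))
  if (!length(colors)) return(state)
  idx <- suppressWarnings(as.integer(base::names(colors)))
  kmax <- length(state@clusterStack)
  if (anyNA(idx) || any(idx < 1L) || any(idx > kmax))
    avValueError("palette indices must be in 1..%d", kmax)
  cols <- as.character(colors)
  bad <- !grepl("^#[0-9A-Fa-f]{6}$", cols)
  if (any(bad)) avValueError("malformed hex color '%s' (expected #RRGGBB)", cols[bad][1])
  state@palette[idx] <- toupper(cols)
  state
}

#' Tooltip text for an individual's bar
#'
#' Lists the individual's population label (when labels exist) and each
#' cluster's display name with its membership proportion at fixed
#' 3-decimal formatting, in the current stack order from top to bottom.
#'
#' @param bundle a [ModeBundle-class].
#' @param mode a mode label.
#' @param individual individual index (1-based, original file order).
#' @param state a [ViewState-class].
#' @return a single string with one line per cluster.
#' @export
tooltipText <- function(bundle, mode, individual, state) {
  m <- getMode(bundle, mode)
  if (length(individual) != 1L || is.na(individual) ||
      individual < 1L || individual > bundle@nInd)
    avLookupError("individual index must be in 1..%d", bundle@nInd)
  q <- qMatrix(m)[individual, ]
  head <- if (hasPopLabels(bundle))
    sprintf("Individual %d (%s)", individual, bundle@labels[individual])
  else sprintf("Individual %d", individual)
  stack <- rev(state@clusterStack)            # top-down display order
  stack <- stack[stack <= m@k]
  body <- sprintf("%s: %.3f", state@clusterNames[stack], q[stack])
  paste(c(head, body), collapse = "\n")
}

#' Tooltip text for an alignment edge
#'
#' @param modeA,modeB the two mode labels.
#' @param cost the alignment cost (lower = better alignment).
#' @return a single string quoting the cost at 3 decimals.
#' @export
edgeTooltipText <- function(modeA, modeB, cost) {
  sprintf("%s - %s: alignment cost %.3f", modeA, modeB, cost)
}
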