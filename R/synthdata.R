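## Synthetic aligned-clustering bundle generator: Dirichlet admixture
## proportions around per-population centers at Kmax, lower-K modes by
## merging correlated cluster columns (so cluster identity is consistent
## across K), minor modes as perturbed alternative merges, run counts
## with a strict major-mode maximum, and alignment costs as the mean
## absolute difference after column collapse. Everything is reproducible
## from the seed.

rdirichlet <- function(n, alpha) {
  # standard gamma construction
  x <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  s <- rowSums(x)
  zero <- s == 0
  if (any(zero)) {               # numerical underflow guard at tiny alpha
    x[zero, ] <- rep(alpha / sum(alpha), each = sum(zero))
    s[zero] <- 1
  }
  x / rowSums(x)
}

#' Specify a synthetic aligned-clustering bundle
#'
#' @param populationSizes named integer vector, individuals per
#'   population; names become the population labels.
#' @param kValues ascending integers >= 2, the K values to generate.
#' @param modesPerK integer, number of modes per K; either a scalar or a
#'   vector named by K. Rank 1 is the major mode.
#' @param concentration positive Dirichlet sharpness: individual
#'   memberships are drawn from Dirichlet(center * concentration) around
#'   their population's center, so larger values put individuals closer
#'   to the center.
#' @param noise perturbation weight in \[0, 1) applied to minor modes
#'   (simplex-preserving mixture with a flat Dirichlet draw; rows
#'   renormalized). Major modes are exact merges and carry no noise.
#' @param runsPerK optional total run count per K (scalar or named by
#'   K), partitioned deterministically over that K's modes with a strict
#'   maximum at rank 1; when `NULL`, counts are drawn from the seed.
#' @param seed integer random seed; the whole bundle is a deterministic
#'   function of the spec including this seed.
#' @return a `SynthSpec` list, validated.
#' @export
synthSpec <- function(populationSizes = c(POP1 = 50, POP2 = 50, POP3 = 50, POP4 = 50),
                      kValues = 2:5, modesPerK = c(`2` = 1, `3` = 1, `4` = 2, `5` = 1),
                      concentration = 50, noise = 0.05, runsPerK = NULL,
                      seed = 1L) {
  kValues <- as.integer(kValues)
  if (is.null(names(populationSizes)) || any(!nzchar(names(populationSizes))))
    avValueError("populationSizes must be a named vector")
  if (any(populationSizes < 1L)) avValueError("population sizes must be >= 1")
  if (!length(kValues) || any(kValues < 2L) || is.unsorted(kValues, strictly = TRUE))
    avValueError("kValues must be strictly ascending integers >= 2")
  expandPerK <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (length(x) == 1L && is.null(names(x)))
      return(stats::setNames(rep(as.integer(x), length(kValues)), kValues))
    if (!all(as.character(kValues) %in% names(x)))
      avValueError("%s must be named by every K value", what)
    stats::setNames(as.integer(x[as.character(kValues)]), kValues)
  }
  modesPerK <- expandPerK(modesPerK, "modesPerK")
  if (any(modesPerK < 1L)) avValueError("modesPerK must be >= 1 for every K")
  runsPerK <- expandPerK(runsPerK, "runsPerK")
  if (concentration <= 0) avValueError("concentration must be positive")
  if (noise < 0 || noise >= 1) avValueError("noise must be in [0, 1)")
  structure(list(
    n_individuals = sum(as.integer(populationSizes)),
    populationSizes = stats::setNames(as.integer(populationSizes),
                                      names(populationSizes)),
    kValues = kValues, modesPerK = modesPerK, concentration = concentration,
    noise = noise, runsPerK = runsPerK, seed = as.integer(seed)
  ), class = "SynthSpec")
}

# merge columns a<b of Q: summed column replaces position a, higher
# columns shift down one index
mergeColumns <- function(Q, a, b) {
  Q[, a] <- Q[, a] + Q[, b]
  Q[, -b, drop = FALSE]
}

# candidate merge pairs of a k-column matrix, ordered by decreasing
# column correlation (ties: lowest (a, b)); constant columns get -Inf
rankedMergePairs <- function(Q) {
  k <- ncol(Q)
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  cc <- suppressWarnings(stats::cor(Q))
  score <- cc[pairs]
  score[is.na(score)] <- -Inf
  ord <- order(-score, pairs[, 1], pairs[, 2])
  pairs[ord, , drop = FALSE]
}

# mean absolute difference between a lower-K matrix and a higher-K
# matrix with its best merge collapsed (brute force over merge pairs)
collapseCost <- function(Qlow, Qhigh) {
  pairs <- which(upper.tri(matrix(0, ncol(Qhigh), ncol(Qhigh))), arr.ind = TRUE)
  best <- Inf
  for (p in seq_len(nrow(pairs))) {
    m <- mergeColumns(Qhigh, pairs[p, 1], pairs[p, 2])
    best <- min(best, mean(abs(Qlow - m)))
  }
  best
}

# deterministic partition of total runs over m ranks, non-increasing
# with a strict maximum at rank 1
partitionRuns <- function(total, m) {
  if (total < m) avValueError("cannot assign %d runs to %d modes", total, m)
  counts <- rep(total %/% m, m)
  rem <- total - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  if (m > 1L && counts[1] == counts[2]) {
    if (counts[m] <= 1L)
      avValueError("cannot give the major mode strictly the most of %d runs over %d modes",
                   total, m)
    counts[1] <- counts[1] + 1L
    counts[m] <- counts[m] - 1L
  }
  as.integer(counts)
}

#' Generate a synthetic aligned-clustering bundle
#'
#' Emulates the output of a clustering-alignment pipeline without
#' running any clustering: (a) at the largest K, each population gets a
#' center drawn from a flat Dirichlet over the simplex and each
#' individual draws its memberships from Dirichlet(center *
#' concentration); (b) each lower-K major mode is derived from the
#' major mode one K above by merging the two most-correlated cluster
#' columns (summing them), which keeps cluster identity consistent
#' across K; (c) minor modes use an alternative (next-ranked) merge
#' plus simplex-preserving noise, rows renormalized; (d) run counts are
#' assigned so the rank-1 mode has strictly the most; (e) alignment
#' costs between all adjacent-K mode pairs are the mean absolute
#' difference between the lower-K matrix and the higher-K matrix with
#' its best merge collapsed — exactly 0 for a noise-free merge. The
#' result is fully reproducible from the spec's seed.
#'
#' @param spec a [synthSpec()] object.
#' @return a [ModeBundle-class] with labels and edges.
#' @export
generateBundle <- function(spec) {
  if (!inherits(spec, "SynthSpec")) spec <- do.call(synthSpec, spec)
  if (max(spec$kValues) < 2L) avValueError("largest K must be >= 2")
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)
  kmax <- max(spec$kValues)
  pops <- names(spec$populationSizes)
  labels <- rep(pops, spec$populationSizes)
  n <- spec$n_individuals

  centers <- rdirichlet(length(pops), rep(1, kmax))
  Qmax <- matrix(0, n, kmax)
  for (p in seq_along(pops)) {
    idx <- which(labels == pops[p])
    Qmax[idx, ] <- rdirichlet(length(idx),
                              pmax(centers[p, ] * spec$concentration, 1e-8))
  }

  # major-mode chain: exact merges downward from Kmax
  majors <- stats::setNames(vector("list", kmax), as.character(seq_len(kmax)))
  majors[[as.character(kmax)]] <- Qmax
  if (kmax > 2L) for (k in seq(kmax - 1L, 2L)) {
    parent <- majors[[as.character(k + 1L)]]
    pr <- rankedMergePairs(parent)
    majors[[as.character(k)]] <- mergeColumns(parent, pr[1, 1], pr[1, 2])
  }

  perturb <- function(Q) {
    if (spec$noise == 0) return(Q)
    (1 - spec$noise) * Q + spec$noise * rdirichlet(nrow(Q), rep(1, ncol(Q)))
  }

  modes <- list()
  for (k in spec$kValues) {
    m <- spec$modesPerK[[as.character(k)]]
    runs <- if (!is.null(spec$runsPerK)) {
      partitionRuns(spec$runsPerK[[as.character(k)]], m)
    } else {
      r <- sort(sample.int(10L, m, replace = TRUE), decreasing = TRUE)
      if (m > 1L && r[1] == r[2]) r[1] <- r[1] + 1L
      r
    }
    for (rank in seq_len(m)) {
      Q <- if (rank == 1L) {
        majors[[as.character(k)]]
      } else if (k < kmax) {
        parent <- majors[[as.character(k + 1L)]]
        pr <- rankedMergePairs(parent)
        alt <- 2L + (rank - 2L) %% (nrow(pr) - 1L)  # a merge other than the major's
        perturb(mergeColumns(parent, pr[alt, 1], pr[alt, 2]))
      } else {
        perturb(majors[[as.character(kmax)]])
      }
      Q <- Q / rowSums(Q)
      modes[[length(modes) + 1L]] <- Mode(k, rank, runs[rank], Q)
    }
  }

  # alignment costs for every adjacent-K mode pair
  edges <- list()
  ks <- vapply(modes, function(m) m@k, integer(1))
  for (i in seq_along(spec$kValues)[-length(spec$kValues)]) {
    klo <- spec$kValues[i]; khi <- spec$kValues[i + 1L]
    if (khi - klo != 1L) next
    for (lo in which(ks == klo)) for (hi in which(ks == khi)) {
      edges[[length(edges) + 1L]] <- data.frame(
        modeA = modes[[lo]]@label, modeB = modes[[hi]]@label,
        cost = collapseCost(modes[[lo]]@Q, modes[[hi]]@Q),
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else NULL
  ModeBundle(modes, labels = labels, edges = edges)
}

#' Write a bundle to disk in an io dialect
#'
#' Emits files such that `discoverBundle(root, dialect)` reproduces the
#' bundle: matrices within 1e-6 (fixed 6-decimal text), identical
#' labels, run counts, and edges (costs within 1e-6).
#'
#' @param bundle a [ModeBundle-class].
#' @param root output directory (created if needed).
#' @param dialect one of `"clumppling"`, `"pong"`, `"plain"`.
#' @return invisibly, `root`.
#' @export
writeBundle <- function(bundle, root, dialect = c("clumppling", "pong", "plain")) {
  stopifnot(is(bundle, "ModeBundle"))
  dialect <- match.arg(dialect)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(root)) avIOError("cannot create directory %s", root)
  labs <- modeLabels(bundle)
  files <- paste0(labs, ".Q")
  for (i in seq_along(bundle@modes))
    writeQMatrix(bundle@modes[[i]]@Q, file.path(root, files[i]))
  runs <- vapply(bundle@modes, function(m) m@runs, integer(1))
  if (dialect == "clumppling") {
    writeLines(sprintf("%s %d", labs, runs), file.path(root, "modes.txt"))
  } else if (dialect == "plain") {
    manifest <- lapply(seq_along(labs), function(i)
      list(label = labs[i], path = files[i], runs = runs[i]))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
               file.path(root, "manifest.json"))
  } else {
    ks <- vapply(bundle@modes, function(m) m@k, integer(1))
    rows <- unlist(lapply(seq_along(labs), function(i)
      sprintf("%s_r%d\t%d\t%s", labs[i], seq_len(runs[i]), ks[i], files[i])))
    writeLines(rows, file.path(root, "filemap.txt"))
  }
  if (length(bundle@labels))
    writeLines(bundle@labels, file.path(root, "labels.txt"))
  if (nrow(bundle@edges))
    writeLines(sprintf("%s %s %.6f", bundle@edges$modeA, bundle@edges$modeB,
                       bundle@edges$cost),
               file.path(root, "alignments.txt"))
  invisible(root)
}
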