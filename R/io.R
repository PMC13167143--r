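## Readers and writers for the three input dialects: membership (Q) matrix
## files, per-individual population label files, and mode-pair alignment
## cost files; plus bundle discovery from Clumppling- or Pong-style output
## directories.

#' Read a membership (Q) matrix file
#'
#' Parses whitespace-delimited numeric text with one row per individual
#' and one column per cluster, the convention used by ADMIXTURE `.Q`
#' files and by the aligned-mode output of Clumppling and Pong. Rows
#' whose sum deviates from 1 by at most `normalizeTol` (upstream tools
#' print rounded proportions) are rescaled to sum exactly to 1; larger
#' deviations signal a wrong file and are an error.
#'
#' @param path path to the matrix file.
#' @param normalizeTol maximum tolerated row-sum deviation from 1
#'   before rescaling (default 0.05).
#' @return a numeric N x K matrix whose rows sum exactly to 1.
#' @examples
#' f <- tempfile(fileext = ".Q")
#' writeLines(c("0.30 0.70", "0.52 0.48"), f)
#' readQMatrix(f)
#' @export
readQMatrix <- function(path, normalizeTol = 0.05) {
  if (!file.exists(path)) avIOError("Q-matrix file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (!length(keep)) avFormatError("no data rows in %s", path)
  toks <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  lens <- lengths(toks)
  if (length(unique(lens)) > 1L) {
    bad <- which(lens != lens[1])[1]
    avFormatError("ragged row in %s: line %d has %d fields, expected %d",
                  path, keep[bad], lens[bad], lens[1])
  }
  vals <- suppressWarnings(vapply(toks, as.numeric, numeric(lens[1])))
  m <- if (lens[1] == 1L) matrix(vals, ncol = 1L) else t(vals)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1, any))[1]
    avFormatError("non-numeric field in %s at line %d", path, keep[bad])
  }
  if (any(m < 0)) avValueError("negative membership coefficient in %s", path)
  rs <- rowSums(m)
  if (any(rs == 0))
    avValueError("row %d of %s sums to 0", keep[which(rs == 0)[1]], path)
  dev <- abs(rs - 1)
  if (any(dev > normalizeTol))
    avValueError("row %d of %s sums to %.6f (deviates from 1 by more than %g)",
                 keep[which.max(dev)], path, rs[which.max(dev)], normalizeTol)
  m <- m / rs
  dimnames(m) <- NULL
  m
}

#' Write a membership matrix to a file
#'
#' Whitespace-delimited text at fixed 6-decimal precision, so that
#' `readQMatrix(writeQMatrix(m))` reproduces the values within 1e-6.
#'
#' @param matrix numeric N x K membership matrix with rows summing to 1.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeQMatrix <- function(matrix, path) {
  validateQMatrix(matrix)
  lines <- apply(matrix, 1, function(r) paste(sprintf("%.6f", r), collapse = " "))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) avIOError("cannot write Q matrix to %s", path)
  invisible(path)
}

#' Read a population label file
#'
#' One individual per line, in the same order as the rows of every Q
#' matrix. The first whitespace-separated token on each line is the
#' population label (extra columns, e.g. an individual id in a
#' two-column `id pop` export, are ignored); lines starting with `#`
#' are skipped.
#'
#' @param path path to the label file.
#' @param nExpected expected number of individuals.
#' @return list with `labels` (character, length `nExpected`) and
#'   `populationOrder` (distinct labels in order of first appearance).
#' @export
readPopLabels <- function(path, nExpected) {
  if (!file.exists(path)) avIOError("label file not found: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  labs <- vapply(strsplit(lines, "[[:space:]]+"), `[[`, character(1), 1L)
  if (length(labs) != nExpected)
    avValueError("label file %s has %d entries but %d individuals expected",
                 path, length(labs), nExpected)
  list(labels = labs, populationOrder = unique(labs))
}

#' Read a mode-pair alignment cost file
#'
#' One edge per line: two mode labels and a non-negative cost, separated
#' by whitespace or commas (Clumppling-style alignment quality listing;
#' lower cost = better alignment). When the same unordered mode pair
#' occurs more than once the last occurrence wins, with a warning, since
#' upstream files may append refinements.
#'
#' @param path path to the alignment file.
#' @return data.frame with columns `modeA`, `modeB`, `cost`, in file order.
#' @export
readAlignmentFile <- function(path) {
  if (!file.exists(path)) avIOError("alignment file not found: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  if (!length(keep)) return(emptyEdges())
  toks <- strsplit(lines[keep], "[,[:space:]]+")
  lens <- lengths(toks)
  if (any(lens != 3L))
    avFormatError("alignment file %s line %d: expected 'modeA modeB cost'",
                  path, keep[which(lens != 3L)[1]])
  a <- vapply(toks, `[[`, character(1), 1L)
  b <- vapply(toks, `[[`, character(1), 2L)
  cost <- suppressWarnings(as.numeric(vapply(toks, `[[`, character(1), 3L)))
  if (anyNA(cost))
    avFormatError("alignment file %s line %d: unparsable cost",
                  path, keep[which(is.na(cost))[1]])
  if (any(cost < 0))
    avValueError("alignment file %s line %d: negative cost",
                 path, keep[which(cost < 0)[1]])
  if (any(a == b))
    avValueError("alignment file %s line %d: self-edge",
                 path, keep[which(a == b)[1]])
  key <- ifelse(a < b, paste(a, b), paste(b, a))
  if (anyDuplicated(key)) {
    warning(sprintf("alignment file %s: %d duplicate mode pair(s); keeping last occurrence",
                    path, sum(duplicated(key))), call. = FALSE)
    last <- !duplicated(key, fromLast = TRUE)
    a <- a[last]; b <- b[last]; cost <- cost[last]
  }
  data.frame(modeA = a, modeB = b, cost = cost, stringsAsFactors = FALSE)
}

parseModeStem <- function(stems) {
  m <- regmatches(stems, regexec("^K([0-9]+)M([0-9]+)$", stems))
  ok <- lengths(m) == 3L
  k <- rep(NA_integer_, length(stems)); r <- rep(NA_integer_, length(stems))
  k[ok] <- as.integer(vapply(m[ok], `[[`, character(1), 2L))
  r[ok] <- as.integer(vapply(m[ok], `[[`, character(1), 3L))
  data.frame(stem = stems, k = k, rank = r, ok = ok, stringsAsFactors = FALSE)
}

readRunCounts <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[,[:space:]]+")
  if (any(lengths(toks) < 2L))
    avFormatError("mode summary %s: expected 'label count' per line", path)
  counts <- suppressWarnings(as.integer(vapply(toks, `[[`, character(1), 2L)))
  if (anyNA(counts)) avFormatError("mode summary %s: unparsable run count", path)
  stats::setNames(counts, vapply(toks, `[[`, character(1), 1L))
}

discoverClumppling <- function(root, normalizeTol) {
  files <- list.files(root, pattern = "^K[0-9]+M[0-9]+\\.(Q|txt)$")
  stems <- sub("\\.(Q|txt)$", "", files)
  if (anyDuplicated(stems))
    avValueError("duplicate mode label '%s' in %s (multiple files share the stem)",
                 stems[duplicated(stems)][1], root)
  info <- parseModeStem(stems)
  if (!nrow(info)) return(NULL)
  runs <- rep(1L, nrow(info))
  modesFile <- file.path(root, "modes.txt")
  if (file.exists(modesFile)) {
    rc <- readRunCounts(modesFile)
    hit <- match(info$stem, names(rc))
    runs[!is.na(hit)] <- rc[hit[!is.na(hit)]]
  }
  lapply(seq_len(nrow(info)), function(i) {
    Q <- readQMatrix(file.path(root, files[i]), normalizeTol)
    if (ncol(Q) != info$k[i])
      avValueError("%s has %d columns but its name declares K=%d",
                   files[i], ncol(Q), info$k[i])
    Mode(info$k[i], info$rank[i], runs[i], Q)
  })
}

discoverPlain <- function(root, normalizeTol) {
  manifest <- file.path(root, "manifest.json")
  if (!file.exists(manifest)) avIOError("plain dialect requires %s", manifest)
  entries <- jsonlite::fromJSON(manifest, simplifyDataFrame = FALSE)
  if (!length(entries)) return(NULL)
  lapply(entries, function(e) {
    info <- parseModeStem(e$label)
    if (!info$ok) avValueError("manifest label '%s' is not of the form K{k}M{m}", e$label)
    runs <- if (is.null(e$runs)) 1L else as.integer(e$runs)
    Q <- readQMatrix(file.path(root, e$path), normalizeTol)
    if (ncol(Q) != info$k)
      avValueError("%s has %d columns but its label declares K=%d",
                   e$path, ncol(Q), info$k)
    Mode(info$k, info$rank, runs, Q)
  })
}

discoverPong <- function(root, normalizeTol) {
  fm <- file.path(root, "filemap.txt")
  if (!file.exists(fm)) avIOError("pong dialect requires %s", fm)
  lines <- trimws(readLines(fm, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(toks) < 3L))
    avFormatError("filemap %s: expected 'runid K path' per line", fm)
  k <- suppressWarnings(as.integer(vapply(toks, `[[`, character(1), 2L)))
  if (anyNA(k)) avFormatError("filemap %s: unparsable K", fm)
  rel <- vapply(toks, `[[`, character(1), 3L)
  # rows sharing a matrix file are runs aligned to the same mode
  firstSeen <- !duplicated(rel)
  paths <- rel[firstSeen]
  kk <- k[firstSeen]
  for (p in paths) {
    kp <- unique(k[rel == p])
    if (length(kp) > 1L)
      avValueError("filemap %s: file %s listed under multiple K values", fm, p)
  }
  runs <- as.integer(table(rel)[paths])
  modes <- vector("list", length(paths))
  for (kv in unique(kk)) {
    idx <- which(kk == kv)
    idx <- idx[order(-runs[idx], seq_along(idx))]  # rank by run count, stable
    for (r in seq_along(idx)) {
      i <- idx[r]
      Q <- readQMatrix(file.path(root, paths[i]), normalizeTol)
      if (ncol(Q) != kv)
        avValueError("%s has %d columns but the filemap declares K=%d",
                     paths[i], ncol(Q), kv)
      modes[[i]] <- Mode(kv, r, runs[i], Q)
    }
  }
  modes
}

#' Discover a mode bundle from an output directory
#'
#' Scans a directory of aligned-clustering output and assembles a
#' [ModeBundle-class]. Three dialects are supported:
#' \describe{
#'   \item{clumppling}{files named `K{k}M{m}.Q` (or `.txt`); run counts
#'     from an optional `modes.txt` with lines `label count`, else 1.}
#'   \item{pong}{a `filemap.txt` with lines `runid K path`; rows sharing
#'     a matrix file are runs of one mode, and modes within each K are
#'     ranked by run count (ties keep filemap order).}
#'   \item{plain}{an explicit `manifest.json`, a JSON array of
#'     `{"label", "path", "runs"}` objects.}
#' }
#' A `labels.txt` (or `labelsPath`) supplies population labels and an
#' `alignments.txt` (or `alignmentPath`) supplies mode-pair alignment
#' costs; both are optional. Discovery is deterministic: modes are
#' sorted by (K, mode rank) regardless of filesystem listing order.
#'
#' @param root directory containing the output files.
#' @param dialect one of `"clumppling"`, `"pong"`, `"plain"`.
#' @param labelsPath optional explicit path to a population label file.
#' @param alignmentPath optional explicit path to an alignment cost file.
#' @param normalizeTol row-sum tolerance passed to [readQMatrix()].
#' @return a [ModeBundle-class].
#' @export
discoverBundle <- function(root, dialect = c("clumppling", "pong", "plain"),
                           labelsPath = NULL, alignmentPath = NULL,
                           normalizeTol = 0.05) {
  dialect <- match.arg(dialect)
  if (!dir.exists(root)) avIOError("input directory not found: %s", root)
  modes <- switch(dialect,
    clumppling = discoverClumppling(root, normalizeTol),
    pong = discoverPong(root, normalizeTol),
    plain = discoverPlain(root, normalizeTol))
  if (is.null(modes) || !length(modes))
    avIOError("no mode matrices found in %s (dialect '%s')", root, dialect)
  ns <- vapply(modes, function(m) nrow(m@Q), integer(1))
  if (length(unique(ns)) > 1L)
    avValueError("membership matrices disagree on the number of individuals: %s",
                 paste(sort(unique(ns)), collapse = ", "))
  labels <- character(0)
  if (is.null(labelsPath)) {
    cand <- file.path(root, "labels.txt")
    if (file.exists(cand)) labelsPath <- cand
  }
  if (!is.null(labelsPath))
    labels <- readPopLabels(labelsPath, ns[1])$labels
  edges <- NULL
  if (is.null(alignmentPath)) {
    cand <- file.path(root, "alignments.txt")
    if (file.exists(cand)) alignmentPath <- cand
  }
  if (!is.null(alignmentPath)) edges <- readAlignmentFile(alignmentPath)
  ModeBundle(modes, labels = labels, edges = edges)
}
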