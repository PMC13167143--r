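# Fixtures are built in code: small hand-made bundles plus random
# generators under fixed seeds.

randomQ <- function(n, k) {
  m <- matrix(runif(n * k), n, k)
  m / rowSums(m)
}

# small bundle: N = 6, K in {2, 3}, one minor mode, non-contiguous labels
tinyBundle <- function(labels = c("A", "A", "B", "B", "B", "A"),
                       withEdges = TRUE) {
  set.seed(42)
  edges <- if (withEdges)
    data.frame(modeA = c("K2M1", "K2M1"), modeB = c("K3M1", "K3M2"),
               cost = c(0.1, 0.4), stringsAsFactors = FALSE)
  else NULL
  ModeBundle(
    list(Mode(2, 1, 5, randomQ(6, 2)),
         Mode(3, 1, 3, randomQ(6, 3)),
         Mode(3, 2, 1, randomQ(6, 3))),
    labels = labels, edges = edges)
}

# brute-force dominance-sort oracle: explicit column sums, argmax with
# lowest-index ties, stable descending sort, blocks concatenated in
# population order
oracleDominance <- function(Q, labels, popOrder) {
  out <- integer(0)
  for (p in popOrder) {
    idx <- which(labels == p)
    if (!length(idx)) next
    sums <- vapply(seq_len(ncol(Q)), function(c) sum(Q[idx, c]), numeric(1))
    d <- which(sums == max(sums))[1]
    mem <- Q[idx, d]
    block <- idx
    # insertion-style stable sort by descending membership
    ord <- seq_along(block)
    ord <- ord[order(-mem, block)]
    out <- c(out, block[ord])
  }
  out
}

countMatches <- function(pattern, x, ...) {
  m <- gregexpr(pattern, x, ...)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

extractBars <- function(svg) {
  regmatches(svg, gregexpr('(?s)<g class="bar".*?</g>', svg, perl = TRUE))[[1]]
}

expect_permutation <- function(perm, n) {
  expect_identical(sort(as.integer(perm)), seq_len(n))
}
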