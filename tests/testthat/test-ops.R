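test_that("dominance sort matches hand-computed example and is stable", {
  Q <- rbind(c(0.2, 0.8), c(0.9, 0.1), c(0.5, 0.5))
  b <- ModeBundle(list(Mode(2, 1, 1, Q)), labels = rep("P", 3))
  s <- defaultView(b)
  s <- sortByClusterDominance(b, "K2M1", s)
  # column sums (1.6, 1.4) -> dominant cluster 1; sort 0.9, 0.5, 0.2
  expect_identical(indOrder(s), c(2L, 3L, 1L))

  # all-identical rows: stable, identity ordering
  Q <- matrix(rep(c(1, 0), each = 4), 4, 2)
  b <- ModeBundle(list(Mode(2, 1, 1, Q)), labels = rep("P", 4))
  s <- sortByClusterDominance(b, "K2M1", defaultView(b))
  expect_identical(indOrder(s), 1:4)
})

test_that("dominance sort is idempotent and matches the brute-force oracle", {
  set.seed(99)
  for (rep in 1:40) {
    n <- sample(3:50, 1)
    k <- sample(2:8, 1)
    npop <- sample(1:min(5, n), 1)
    labels <- sample(paste0("P", seq_len(npop)), n, replace = TRUE)
    labels[seq_len(npop)] <- paste0("P", seq_len(npop))  # every pop non-empty
    b <- ModeBundle(list(Mode(k, 1, 1, randomQ(n, k))), labels = labels)
    s <- defaultView(b)
    s1 <- sortByClusterDominance(b, sprintf("K%dM1", k), s)
    expect_permutation(indOrder(s1), n)
    expect_identical(indOrder(s1),
                     oracleDominance(qMatrix(bundleModes(b)[[1]]), labels, s@popOrder))
    s2 <- sortByClusterDominance(b, sprintf("K%dM1", k), s1)
    expect_identical(indOrder(s2), indOrder(s1))
    # within each block, membership in the block's dominant cluster is non-increasing
    Q <- qMatrix(bundleModes(b)[[1]])
    for (p in s1@popOrder) {
      idx <- which(labels == p)
      d <- which.max(colSums(Q[idx, , drop = FALSE]))
      mem <- Q[intersect(indOrder(s1), idx), d]
      expect_true(all(diff(mem) <= 1e-12))
    }
  }
})

test_that("dominance sort rejects unknown modes", {
  b <- tinyBundle()
  expect_error(sortByClusterDominance(b, "K9M1", defaultView(b)),
               class = "avLookupError")
})

test_that("reorderPopulations swaps blocks and preserves within-block order", {
  b <- tinyBundle(labels = c("A", "A", "B", "B", "B", "A"))
  s <- defaultView(b)
  s2 <- reorderPopulations(b, s, c("B", "A"))
  expect_identical(s2@popOrder, c("B", "A"))
  expect_identical(indOrder(s2), c(3L, 4L, 5L, 1L, 2L, 6L))

  # identity reorder keeps the (effective) ordering
  s3 <- reorderPopulations(b, s, c("A", "B"))
  expect_identical(indOrder(s3), c(1L, 2L, 6L, 3L, 4L, 5L))
  expect_identical(s3@popOrder, s@popOrder)

  expect_error(reorderPopulations(b, s, c("A", "C")), class = "avValueError")
  expect_error(reorderPopulations(b, s, c("A", "A", "B")), class = "avValueError")

  noLabels <- ModeBundle(list(Mode(2, 1, 1, randomQ(4, 2))))
  expect_error(reorderPopulations(noLabels, defaultView(noLabels), "ALL"),
               class = "avFeatureDisabledError")
})

test_that("random population permutations equal explicit block concatenation", {
  set.seed(17)
  for (rep in 1:15) {
    n <- 30
    labels <- sample(paste0("P", 1:5), n, replace = TRUE)
    labels[1:5] <- paste0("P", 1:5)
    b <- ModeBundle(list(Mode(2, 1, 1, randomQ(n, 2))), labels = labels)
    s <- defaultView(b)
    ord <- sample(s@popOrder)
    s2 <- reorderPopulations(b, s, ord)
    expected <- unlist(lapply(ord, function(p) which(labels == p)))
    expect_identical(indOrder(s2), as.integer(expected))
    expect_permutation(indOrder(s2), n)
  }
})

test_that("reorderClusters stores the reversed (bottom-up) stack", {
  b <- ModeBundle(list(Mode(2, 1, 1, randomQ(3, 2))))
  s <- reorderClusters(defaultView(b), c(2, 1))
  expect_identical(s@clusterStack, c(1L, 2L))  # top-down (2,1) -> bottom-up (1,2)

  b3 <- tinyBundle()
  s <- reorderClusters(defaultView(b3), c(2, 3, 1))  # cluster 2 at top
  expect_identical(s@clusterStack[3], 2L)            # last in bottom-up order
  expect_error(reorderClusters(s, c(1, 1, 2)), class = "avValueError")
})

test_that("cluster reordering conserves per-individual totals and tooltip proportions", {
  b <- tinyBundle()
  s <- defaultView(b)
  tipBefore <- tooltipText(b, "K3M1", 2, s)
  set.seed(5)
  for (rep in 1:10) {
    s2 <- reorderClusters(s, sample(3))
    for (m in bundleModes(b))
      expect_equal(rowSums(qMatrix(m)), rep(1, 6), tolerance = 1e-12)
    # same proportions appear in the tooltip regardless of stack order
    nums <- sort(regmatches(tooltipText(b, "K3M1", 2, s2),
                            gregexpr("0\\.[0-9]{3}", tooltipText(b, "K3M1", 2, s2)))[[1]])
    numsBefore <- sort(regmatches(tipBefore, gregexpr("0\\.[0-9]{3}", tipBefore))[[1]])
    expect_identical(nums, numsBefore)
  }
})

test_that("highlight sets, clears, and guards the index range", {
  b <- tinyBundle()
  s <- defaultView(b)
  s <- highlightCluster(s, 3)
  expect_identical(s@highlight, 3L)
  s <- highlightCluster(s, NULL)
  expect_true(is.na(s@highlight))
  expect_error(highlightCluster(s, 4), class = "avValueError")
  expect_error(highlightCluster(s, 0), class = "avValueError")
})

test_that("hideMinorModes keeps exactly the rank-1 mode per K and is idempotent", {
  b <- tinyBundle()
  majors <- hideMinorModes(b)
  expect_identical(vapply(majors, modeLabel, character(1)), c("K2M1", "K3M1"))
  b2 <- ModeBundle(majors, labels = popLabels(b))
  expect_identical(vapply(hideMinorModes(b2), modeLabel, character(1)),
                   c("K2M1", "K3M1"))
  expect_length(majors, length(kValues(b)))
})

test_that("renameClusters updates names and keeps defaults elsewhere", {
  b <- tinyBundle()
  s <- renameClusters(defaultView(b), character(0))
  expect_identical(s@clusterNames, paste("Cluster", 1:3))
  s <- renameClusters(s, c("1" = "African"))
  expect_identical(s@clusterNames, c("African", "Cluster 2", "Cluster 3"))
  expect_match(tooltipText(b, "K3M1", 1, s), "African: ")
  expect_error(renameClusters(s, c("9" = "x")), class = "avValueError")
})

test_that("setPalette validates hex colors and overrides selectively", {
  b <- tinyBundle()
  s <- defaultView(b)
  before <- s@palette
  s2 <- setPalette(s, c("2" = "#ff0000"))
  expect_identical(s2@palette[2], "#FF0000")
  expect_identical(s2@palette[-2], before[-2])
  expect_identical(setPalette(s, character(0))@palette, before)
  expect_error(setPalette(s, c("1" = "#zz0000")), class = "avValueError")
})

test_that("tooltips report memberships at 3 decimals in stack order", {
  Q <- rbind(c(0.25, 0.75))
  b <- ModeBundle(list(Mode(2, 1, 1, Q)))
  s <- defaultView(b)
  tip <- tooltipText(b, "K2M1", 1, s)
  expect_match(tip, "Cluster 1: 0.250", fixed = TRUE)
  expect_match(tip, "Cluster 2: 0.750", fixed = TRUE)
  expect_error(tooltipText(b, "K2M1", 5, s), class = "avLookupError")
  expect_match(edgeTooltipText("K4M2", "K5M1", 0.1234), "0.123", fixed = TRUE)
})
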