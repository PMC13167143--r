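test_that("synthSpec validates its inputs", {
  expect_error(synthSpec(populationSizes = c(10, 10)), class = "avValueError")
  expect_error(synthSpec(kValues = c(1, 2)), class = "avValueError")
  expect_error(synthSpec(kValues = c(3, 2)), class = "avValueError")
  expect_error(synthSpec(concentration = 0), class = "avValueError")
  expect_error(synthSpec(noise = 1), class = "avValueError")
  expect_error(synthSpec(modesPerK = 0), class = "avValueError")
  s <- synthSpec(populationSizes = c(A = 5, B = 7))
  expect_identical(s$n_individuals, 12L)
})

test_that("generateBundle is reproducible from the seed", {
  spec <- synthSpec(populationSizes = c(A = 15, B = 15), kValues = 2:4,
                    modesPerK = 2, seed = 21)
  b1 <- generateBundle(spec)
  b2 <- generateBundle(spec)
  expect_identical(modeLabels(b1), modeLabels(b2))
  for (i in seq_along(bundleModes(b1)))
    expect_identical(qMatrix(bundleModes(b1)[[i]]), qMatrix(bundleModes(b2)[[i]]))
  expect_identical(alignmentEdges(b1), alignmentEdges(b2))
  b3 <- generateBundle(synthSpec(populationSizes = c(A = 15, B = 15),
                                 kValues = 2:4, modesPerK = 2, seed = 22))
  expect_false(identical(qMatrix(bundleModes(b1)[[1]]),
                         qMatrix(bundleModes(b3)[[1]])))
})

test_that("generated matrices satisfy membership invariants exactly", {
  b <- generateBundle(synthSpec(populationSizes = c(A = 20, B = 20, C = 20),
                                kValues = 2:6, modesPerK = 2, seed = 5))
  for (m in bundleModes(b)) {
    expect_silent(validateQMatrix(qMatrix(m)))
    expect_identical(ncol(qMatrix(m)), modeK(m))
  }
  expect_identical(popLabels(b), rep(c("A", "B", "C"), each = 20))
})

test_that("run counts are non-increasing with a strict major-mode maximum", {
  for (seed in 1:5) {
    b <- generateBundle(synthSpec(populationSizes = c(A = 10, B = 10),
                                  kValues = 2:5, modesPerK = 3, seed = seed))
    ks <- vapply(bundleModes(b), modeK, integer(1))
    for (k in unique(ks)) {
      runs <- vapply(bundleModes(b)[ks == k], runCount, integer(1))
      expect_true(all(diff(runs) <= 0))
      expect_gt(runs[1], runs[2])
    }
  }
  # explicit per-K totals partition deterministically
  b <- generateBundle(synthSpec(populationSizes = c(A = 10, B = 10),
                                kValues = 2:3, modesPerK = 2, runsPerK = 8,
                                seed = 1))
  runs <- vapply(bundleModes(b), runCount, integer(1))
  expect_identical(sum(runs[1:2]), 8L)
  expect_identical(sum(runs[3:4]), 8L)
  expect_identical(summarizeBundle(b)$total_runs, 16L)
})

test_that("costs are non-negative and exact merges give cost 0", {
  b <- generateBundle(synthSpec(populationSizes = c(A = 25, B = 25),
                                kValues = 2:5, modesPerK = 2, noise = 0.1,
                                seed = 13))
  e <- alignmentEdges(b)
  expect_true(all(e$cost >= 0))
  # the major-mode chain is built by exact column merges: cost exactly 0
  majorPairs <- e[grepl("M1$", e$modeA) & grepl("M1$", e$modeB), ]
  expect_true(nrow(majorPairs) >= 3)
  expect_lt(max(majorPairs$cost), 1e-12)  # exact merges, up to float roundoff
  # perturbed minor modes carry strictly positive cost
  minorPairs <- e[grepl("M2$", e$modeA) | grepl("M2$", e$modeB), ]
  expect_true(all(minorPairs$cost > 1e-6))
})

test_that("high concentration pins individuals near their population centers", {
  b <- generateBundle(synthSpec(populationSizes = c(A = 30, B = 30),
                                kValues = 2:3, modesPerK = 1,
                                concentration = 1e5, seed = 9))
  Q <- qMatrix(getMode(b, "K3M1"))
  labs <- popLabels(b)
  for (p in unique(labs)) {
    block <- Q[labs == p, ]
    center <- colMeans(block)
    expect_lt(max(abs(sweep(block, 2, center))), 0.05)
  }
})

test_that("dominance sorting on a high-concentration bundle recovers population blocks", {
  b <- generateBundle(synthSpec(
    populationSizes = c(P1 = 50, P2 = 50, P3 = 50, P4 = 50),
    kValues = 2:5, modesPerK = 1, concentration = 1e4, seed = 101))
  ref <- sprintf("K%dM1", max(kValues(b)))
  s <- sortByClusterDominance(b, ref, defaultView(b))
  Q <- qMatrix(getMode(b, ref))
  labs <- popLabels(b)
  agree <- vapply(s@popOrder, function(p) {
    idx <- which(labs == p)
    d <- which.max(colSums(Q[idx, , drop = FALSE]))
    mean(apply(Q[idx, , drop = FALSE], 1, which.max) == d)
  }, numeric(1))
  expect_gte(mean(rep(agree, times = table(labs)[s@popOrder])), 0.95)
})

test_that("writeBundle round-trips through every dialect", {
  b <- generateBundle(synthSpec(populationSizes = c(A = 8, B = 8),
                                kValues = 2:4, modesPerK = 2, seed = 6))
  for (dialect in c("clumppling", "plain", "pong")) {
    root <- file.path(withr::local_tempdir(), "bundle")  # created on demand
    writeBundle(b, root, dialect)
    b2 <- discoverBundle(root, dialect)
    expect_identical(modeLabels(b2), modeLabels(b))
    expect_identical(vapply(bundleModes(b2), runCount, integer(1)),
                     vapply(bundleModes(b), runCount, integer(1)))
    expect_identical(popLabels(b2), popLabels(b))
    for (i in seq_along(bundleModes(b)))
      expect_lt(max(abs(qMatrix(bundleModes(b2)[[i]]) -
                        qMatrix(bundleModes(b)[[i]]))), 1e-6)
    e1 <- alignmentEdges(b); e2 <- alignmentEdges(b2)
    expect_identical(e2$modeA, e1$modeA)
    expect_identical(e2$modeB, e1$modeB)
    expect_lt(max(abs(e2$cost - e1$cost)), 1e-6)
    if (dialect == "plain")
      expect_true(file.exists(file.path(root, "manifest.json")))
  }
})
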