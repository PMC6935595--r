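test_that("SUMSTAT is the plain sum of member statistics", {
  stats <- c(g1 = 1.0, g2 = -0.5, g3 = 2.5, g4 = 0.25)
  expect_equal(sumstat(c("g1", "g2", "g3"), stats), 3.0)
  expect_equal(sumstat("g2", stats), -0.5)
  expect_equal(sumstat(names(stats), stats), sum(stats))
  expect_warning(out <- sumstat(c("g1", "nope"), stats), "without statistic")
  expect_equal(out, 1.0)
  expect_error(sumstat(c("g1", "nope"), stats, strict = TRUE), "nope")
})

test_that("a constant statistic universe is reported as degenerate", {
  stats <- setNames(rep(2, 30), sprintf("g%02d", 1:30))
  r <- sumstatTest(sprintf("g%02d", 1:5), stats, nDraws = 2000, seed = 1)
  expect_true(r$degenerate)
  expect_equal(r$pLow, 0.5)
  expect_equal(r$pHigh, 0.5)
})

test_that("null mean matches the without-replacement expectation and tails sum to 1", {
  set.seed(301)
  stats <- setNames(rnorm(100, 1, 2), sprintf("g%03d", 1:100))
  r <- sumstatTest(sprintf("g%03d", 1:8), stats, nDraws = 50000, seed = 2)
  # E[sum of k draws without replacement] = k * mean(universe)
  se <- r$nullSd / sqrt(50000)
  expect_lt(abs(r$nullMean - 8 * mean(stats)), 5 * se)
  expect_equal(r$pLow + r$pHigh, 1, tolerance = 1e-12)
})

test_that("normal-approximation p agrees with exhaustive enumeration", {
  # the discrete 495-atom null keeps the normal fit within ~0.01 of the
  # exact mid-p on average over sets and universes (a single set in a
  # single universe can deviate by the null's KS distance, up to ~0.05)
  set.seed(302)
  gaps <- unlist(lapply(1:8, function(u) {
    stats <- setNames(rnorm(12), sprintf("g%02d", 1:12))
    allSums <- combn(12, 4, function(ix) sum(stats[ix]))  # all 495 subsets
    vapply(1:8, function(rep) {
      set <- sample(names(stats), 4)
      r <- sumstatTest(set, stats, nDraws = 20000)
      obs <- sum(stats[set])
      exact <- mean(allSums < obs) + 0.5 * mean(allSums == obs)
      abs(r$pLow - exact)
    }, 0)
  }))
  expect_lt(mean(gaps), 0.02)
})

test_that("pruning is a no-op for disjoint sets and removes engulfed subsets", {
  set.seed(303)
  stats <- setNames(rnorm(60), sprintf("g%02d", 1:60))
  disjoint <- PathwayCollection(list(A = sprintf("g%02d", 1:6),
                                     B = sprintf("g%02d", 11:16)))
  out <- pruneAndTest(disjoint, stats, side = "high", nDraws = 5000,
                      seed = 4)
  expect_setequal(out$results$set, c("A", "B"))
  expect_equal(out$results$sizeAfter, out$results$sizeBefore)
  expect_true(all(diff(out$results$p) >= 0))       # emitted by ascending p
  expect_false(any(out$results$set %in%
                   out$trace$set[out$trace$event == "pruned_out"]))

  # A contains B entirely: B must be pruned out after A is emitted
  nested <- PathwayCollection(list(A = sprintf("g%02d", 1:10),
                                   B = sprintf("g%02d", 1:5)))
  statsN <- stats
  statsN[sprintf("g%02d", 1:10)] <- statsN[sprintf("g%02d", 1:10)] + 3
  outN <- pruneAndTest(nested, statsN, side = "high", nDraws = 5000,
                       seed = 5)
  expect_equal(outN$results$set, "A")
  expect_true("B" %in% outN$trace$set[outN$trace$event == "pruned_out"])

  # a planted high-sum set is emitted first among several
  u <- simulatePathwayUniverse(nGenes = 200, nSets = 8, setSize = 10,
                               delta = 1.5, seed = 6)
  outP <- pruneAndTest(u$collection, u$stats, side = "high",
                       nDraws = 5000, seed = 7)
  expect_equal(outP$results$set[1], u$truth$planted)
  # termination bookkeeping: each set appears at most once
  expect_false(anyDuplicated(outP$results$set) > 0)
})

test_that("results are bit-identical across runs with the same seed", {
  u <- simulatePathwayUniverse(nGenes = 100, nSets = 4, setSize = 8,
                               delta = 1, seed = 8)
  r1 <- pruneAndTest(u$collection, u$stats, side = "high", nDraws = 3000,
                     seed = 99)
  r2 <- pruneAndTest(u$collection, u$stats, side = "high", nDraws = 3000,
                     seed = 99)
  expect_identical(r1, r2)
  q1 <- empiricalFdr(r1, u$collection, u$stats, side = "high",
                     nDraws = 1000, nIter = 50, seed = 100)
  q2 <- empiricalFdr(r2, u$collection, u$stats, side = "high",
                     nDraws = 1000, nIter = 50, seed = 100)
  expect_identical(q1, q2)
})

test_that("empirical FDR ranks a planted shifted set first and is monotone", {
  u <- simulatePathwayUniverse(nGenes = 200, nSets = 6, setSize = 10,
                               delta = 1.2, seed = 9)
  obs <- pruneAndTest(u$collection, u$stats, side = "high", nDraws = 5000,
                      seed = 10)
  res <- empiricalFdr(obs, u$collection, u$stats, side = "high",
                      nDraws = 5000, nIter = 60, seed = 11)
  expect_equal(res$set[which.min(res$Q)], u$truth$planted)
  o <- order(res$p)
  expect_true(all(diff(res$Q[o]) >= -1e-12))       # non-decreasing in p
  expect_true(all(res$Q >= 0 & res$Q <= 1))
  expect_warning(
    empiricalFdr(obs, u$collection, u$stats, side = "high", nDraws = 500,
                 nIter = 10, seed = 12), "unstable")
})
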