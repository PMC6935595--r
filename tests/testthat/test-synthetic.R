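test_that("coalescent segregating sites match Watterson's expectation", {
  # n = 2: E[S] = theta
  set.seed(501)
  S2 <- replicate(2000, siteSpectrumCounts(
    simulateCoalescentGene(2, 5, 150))$S)
  expect_lt(abs(mean(S2) - 5), 0.3)

  # n = 20: E[S] = theta * a_n, within 3 standard errors
  set.seed(502)
  S20 <- replicate(400, siteSpectrumCounts(
    simulateCoalescentGene(20, 5, 300))$S)
  expS <- 5 * sum(1 / 1:19)
  expect_lt(abs(mean(S20) - expS), 3 * sd(S20) / sqrt(length(S20)))

  # per-site pi scales like theta / L
  set.seed(503)
  piHat <- replicate(300, nucleotideDiversity(
    simulateCoalescentGene(10, 4, 200))$pi)
  expect_lt(abs(mean(piHat) - 4 / 200), 3 * sd(piHat) / sqrt(300))

  # determinism and the L-overflow guard
  a <- simulateCoalescentGene(8, 3, 100, seed = 7)
  b <- simulateCoalescentGene(8, 3, 100, seed = 7)
  expect_identical(alleleMatrix(a), alleleMatrix(b))
  expect_error(simulateCoalescentGene(20, 50, 2, seed = 1), "increase L")
})

test_that("population panels are deterministic and respect their config", {
  cfg <- simulationConfig(nGenes = 25L, snpsPerGeneMean = 3, nSets = 3L)
  p1 <- simulatePopulationPanel(cfg, seed = 504)
  p2 <- simulatePopulationPanel(cfg, seed = 504)
  expect_identical(genotypes(p1$dataset), genotypes(p2$dataset))
  expect_identical(p1$truth$clinalSnps, p2$truth$clinalSnps)

  ds <- p1$dataset
  expect_equal(length(unique(popmap(ds))), 12L)
  expect_equal(ncol(genotypes(ds)), 120L)
  expect_equal(ncol(climateMatrix(ds)), 24L)   # 8 variables x 3 periods
  expect_true(all(lengths(geneSets(ds)) >= 5))
  expect_true(all(genotypes(ds) %in% c(0L, 1L, 2L, NA)))
  # every sample mapped; SNPs all carry a gene
  expect_setequal(colnames(genotypes(ds)), names(popmap(ds)))
  expect_false(anyNA(snpMeta(ds)$gene))

  # external calls: planted SNPs dominate the significant set
  ext <- externalCalls(ds)
  if (nrow(ext) > 0 && nrow(p1$truth$clinalSnps) > 0) {
    planted <- ext$snp %in% p1$truth$clinalSnps$snp
    expect_gt(mean(planted[ext$significant]), 0.5)
  }
})

test_that("a beta = 0 panel produces null-calibrated association scans", {
  cfg <- simulationConfig(nGenes = 100L, snpsPerGeneMean = 4,
                          clinalFraction = 0, nSets = 2L)
  panel <- simulatePopulationPanel(cfg, seed = 505)
  af <- populationAlleleFrequencies(panel$dataset)
  res <- spearmanScan(af, climateMatrix(panel$dataset), alpha = 0.01)
  rate <- mean(res$significant[!is.na(res$p)])
  # nominal 1% with approximation slack at m = 12
  expect_lt(rate, 0.025)
})

test_that("pathway universes plant detectable shifts and engineered overlap", {
  u0 <- simulatePathwayUniverse(nGenes = 120, nSets = 5, setSize = 8,
                                delta = 0, seed = 506)
  expect_equal(length(u0$stats), 120L)
  expect_equal(length(geneSets(u0$collection)), 5L)

  # planted set ranks first by p in most seeds
  hits <- vapply(1:10, function(s) {
    u <- simulatePathwayUniverse(nGenes = 200, nSets = 6, setSize = 10,
                                 delta = 1, seed = 600 + s)
    out <- pruneAndTest(u$collection, u$stats, side = "high",
                        nDraws = 3000)
    out$results$set[1] == u$truth$planted
  }, TRUE)
  expect_gte(mean(hits), 0.8)

  # nested option creates a strict subset of the planted set
  un <- simulatePathwayUniverse(nGenes = 100, nSets = 4, setSize = 10,
                                delta = 0.5, seed = 507, nested = TRUE)
  sets <- geneSets(un$collection)
  expect_true(all(sets[[un$truth$nested]] %in% sets[[un$truth$planted]]))
})
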