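test_that("population allele frequencies are copy counts over genotyped copies", {
  # one pop of 3 diploids: {0/1, 1/1, ./.} -> 3 of 4 copies
  geno <- matrix(c(1L, 2L, NA), 1, 3)
  ds <- makeDataset(geno, rep("p1", 3))
  af <- populationAlleleFrequencies(ds)
  expect_equal(unname(af$freq[1, "p1"]), 0.75)
  expect_equal(unname(af$copies[1, "p1"]), 4L)

  # all reference homozygotes
  ds0 <- makeDataset(matrix(0L, 1, 3), rep("p1", 3))
  expect_equal(unname(populationAlleleFrequencies(ds0)$freq[1, 1]), 0)

  # bounds hold under arbitrary missingness
  set.seed(201)
  g <- matrix(sample(c(0:2, NA), 200, TRUE), 20, 10)
  dsb <- makeDataset(g, rep(c("a", "b"), each = 5))
  f <- populationAlleleFrequencies(dsb)$freq
  expect_true(all(f >= 0 & f <= 1, na.rm = TRUE))
  # fully missing population cell is undefined
  g2 <- g; g2[1, 1:5] <- NA
  f2 <- populationAlleleFrequencies(makeDataset(g2, rep(c("a", "b"),
                                                        each = 5)))$freq
  expect_true(is.na(f2[1, "a"]))
})

test_that("the rank-correlation scan handles monotone, degenerate and tied data", {
  pops <- sprintf("p%02d", 1:12)
  clim <- matrix(1:12, 12, 1, dimnames = list(pops, "tmean_PRE"))
  f <- rbind(mono = seq(0.1, 0.9, length.out = 12),
             flat = rep(0.3, 12))
  colnames(f) <- pops
  res <- spearmanScan(f, clim, alpha = 0.01)
  mono <- res[res$snp == "mono", ]
  expect_equal(mono$rho, 1, tolerance = 1e-12)
  expect_equal(mono$p, 0)
  expect_true(mono$significant)
  flat <- res[res$snp == "flat", ]
  expect_true(is.na(flat$rho))
  expect_false(flat$significant)

  # 8 populations with a tie: mid-rank Pearson + t-CDF oracle
  x <- c(0.1, 0.2, 0.2, 0.35, 0.4, 0.55, 0.6, 0.7)
  y <- c(3, 1, 4, 2, 6, 5, 8, 7)
  f8 <- matrix(x, 1, 8, dimnames = list("s", sprintf("q%d", 1:8)))
  c8 <- matrix(y, 8, 1, dimnames = list(sprintf("q%d", 1:8), "v_PRE"))
  r8 <- spearmanScan(f8, c8)
  rhoExp <- cor(rank(x), rank(y))
  expect_equal(r8$rho, rhoExp, tolerance = 1e-12)
  tExp <- rhoExp * sqrt(6 / (1 - rhoExp^2))
  expect_equal(r8$p, 2 * (1 - pt(abs(tExp), 6)), tolerance = 1e-12)

  # invariance under strictly monotone transforms of climate
  c8b <- c8; c8b[, 1] <- exp(c8[, 1] / 2)
  r8b <- spearmanScan(f8, c8b)
  expect_equal(r8b$rho, r8$rho, tolerance = 1e-12)
  expect_equal(r8b$p, r8$p, tolerance = 1e-12)
})

test_that("gene-level binomial outlier test pools rates over genes with hits", {
  # genes (n, a) = (10, 4), (20, 1), (5, 0): P = 5/30
  assoc <- data.frame(
    snp = sprintf("s%02d", 1:35),
    variable = "tmean", period = "PRE",
    rho = 0.5, p = 0.5, m = 12L,
    significant = c(rep(TRUE, 4), rep(FALSE, 6),    # gene A: 4/10
                    TRUE, rep(FALSE, 19),           # gene B: 1/20
                    rep(FALSE, 5)),                 # gene C: 0/5
    stringsAsFactors = FALSE)
  gm <- setNames(rep(c("A", "B", "C"), c(10, 20, 5)), assoc$snp)
  res <- geneOutlierTest(assoc, gm)
  expect_equal(res$P, rep(5 / 30, 3), tolerance = 1e-12)
  # exact-CDF oracle for the 0.9999 quantile
  qOracle <- function(n, P) {
    q <- 0
    while (sum(dbinom(0:q, n, P)) < 0.9999) q <- q + 1
    q
  }
  for (i in seq_len(nrow(res)))
    expect_equal(res$qThreshold[i], qOracle(res$n[i], res$P[i]))
  expect_equal(res$flagged, res$a > res$qThreshold)
  # a gene with zero hits is reported but can never be flagged
  expect_false(res$flagged[res$gene == "C"])
  expect_equal(res$a[res$gene == "C"], 0L)

  # P -> 0 limit: one huge gene with a single hit drags the pooled rate
  # down, so a small gene's single hit exceeds the 0.9999 quantile (0)
  nBig <- 100000L
  assoc2 <- data.frame(snp = sprintf("t%06d", seq_len(nBig + 3)),
                       variable = "v", period = "PRE", rho = 0, p = 0.5,
                       m = 12L,
                       significant = c(TRUE, rep(FALSE, nBig - 1),
                                       TRUE, FALSE, FALSE))
  gm2 <- setNames(c(rep("big", nBig), rep("tiny", 3)), assoc2$snp)
  res2 <- geneOutlierTest(assoc2, gm2)
  expect_equal(res2$P, rep(2 / (nBig + 3), 2), tolerance = 1e-12)
  tiny <- res2[res2$gene == "tiny", ]
  expect_equal(tiny$qThreshold, 0L)
  expect_true(tiny$flagged)
  expect_false(res2$flagged[res2$gene == "big"])

  # mean-of-ratios alternative
  resM <- geneOutlierTest(assoc, gm, poolRule = "mean-ratio")
  expect_equal(resM$P, rep(mean(c(4 / 10, 1 / 20)), 3), tolerance = 1e-12)

  # no gene with hits: inapplicable
  assoc$significant <- FALSE
  resNone <- geneOutlierTest(assoc, gm)
  expect_equal(nrow(resNone), 0)
  expect_equal(attr(resNone, "status"), "inapplicable")
})

test_that("top-candidate selection needs external support on the same variable", {
  flags <- data.frame(gene = c("erd4", "other"),
                      variable = "pdry", period = "PRE",
                      n = c(6L, 8L), a = c(5L, 3L), P = 0.1,
                      qThreshold = 2L, flagged = c(TRUE, TRUE),
                      stringsAsFactors = FALSE)
  gm <- setNames(c(rep("erd4", 6), rep("other", 8)),
                 sprintf("s%02d", 1:14))
  calls <- data.frame(
    snp = c(sprintf("s%02d", 1:4), sprintf("s%02d", 1:4),
            "s07", "s08", "s09"),
    variable = c(rep("pdry", 8), "pdry", "tmean", "tmean"),
    period = "PRE",
    method = c(rep("baypass", 4), rep("bayescenv", 4),
               "baypass", "baypass", "bayescenv"),
    score = 40, significant = TRUE, stringsAsFactors = FALSE)
  out <- selectTopCandidates(flags, calls, gm, minSnps = 2)
  expect_equal(out$gene, "erd4")
  expect_equal(out$geneLevel, 5L)
  expect_equal(out$nBaypass, 4L)
  expect_equal(out$nBayescenv, 4L)
  # "other" had 1 matching-variable SNP and 2 on a different variable
  expect_false("other" %in% out$gene)
  # output is always a subset of the flagged genes
  expect_true(all(out$gene %in% flags$gene[flags$flagged]))
  # without external calls the flags come back unconfirmed
  un <- selectTopCandidates(flags, data.frame(), gm)
  expect_equal(attr(un, "status"), "unconfirmed")
  expect_equal(un$gene, flags$gene)
})

test_that("planted clines are recovered and nulls stay near the nominal rate", {
  cfg <- simulationConfig(nGenes = 150L, snpsPerGeneMean = 4,
                          clinalFraction = 0.1, beta = 2, nSets = 2L)
  panel <- simulatePopulationPanel(cfg, seed = 202)
  ds <- panel$dataset
  af <- populationAlleleFrequencies(ds)
  res <- spearmanScan(af, climateMatrix(ds), alpha = 0.01)
  truth <- panel$truth$clinalSnps
  key <- paste(res$snp, res$variable, res$period)
  planted <- res[key %in% paste(truth$snp, truth$variable, truth$period), ]
  expect_gte(mean(planted$significant), 0.6)
  # null SNP-variable pairs reject near alpha (t approximation at m = 12)
  nullRes <- res[!res$snp %in% truth$snp, ]
  rate <- mean(nullRes$significant)
  expect_lt(rate, 0.025)
  expect_gt(rate, 0.002)
})
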