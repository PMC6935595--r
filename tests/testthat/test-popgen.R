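test_that("per-site diversity matches hand-enumerated pairwise differences", {
  # one site A,A,T,T: h = (4/3)(1 - 1/2) = 2/3 = 4 differing pairs / 6
  al <- SiteAlignment(matrix(c("A", "A", "T", "T"), 4, 1))
  expect_equal(nucleotideDiversity(al)$pi, 2 / 3, tolerance = 1e-12)
  expect_equal(bruteForcePi(al), 2 / 3, tolerance = 1e-12)

  # monomorphic alignment
  expect_equal(nucleotideDiversity(SiteAlignment(matrix("G", 6, 25)))$pi, 0)

  # one A,T,T,T site among 9 monomorphic sites: pi = 0.5 / 10 = 0.05
  al2 <- SiteAlignment(cbind(matrix("A", 4, 9), c("A", "T", "T", "T")))
  expect_equal(perSiteHeterozygosity(al2)[10], 0.5, tolerance = 1e-12)
  expect_equal(nucleotideDiversity(al2)$pi, 0.05, tolerance = 1e-12)
})

test_that("diversity equals the brute-force pairwise oracle on random data", {
  set.seed(101)
  for (i in 1:60) {
    al <- randomAlignment(sample(4:10, 1), sample(5:50, 1),
                          missRate = runif(1, 0, 0.2))
    expect_equal(nucleotideDiversity(al)$pi, bruteForcePi(al),
                 tolerance = 1e-12)
  }
})

test_that("statistics are invariant to sample and site permutations", {
  set.seed(102)
  al <- randomAlignment(8, 30, 0.15)
  alPerm <- SiteAlignment(alleleMatrix(al)[sample(8), sample(30)])
  for (f in list(function(a) nucleotideDiversity(a)$pi,
                 function(a) unlist(siteSpectrumCounts(a)),
                 function(a) unlist(neutralityStats(a)[1:3]))) {
    expect_equal(f(al), f(alPerm), tolerance = 1e-12)
  }
})

test_that("class diversities are additive when weights partition sites", {
  set.seed(103)
  L <- 40
  w <- matrix(runif(L * 3), L, 3)
  w <- w / rowSums(w)
  al <- SiteAlignment(alleleMatrix(randomAlignment(8, L, 0.1)), weights = w)
  parts <- lapply(c("syn", "nonsyn", "other"),
                  function(cl) nucleotideDiversity(al, cl))
  tot <- nucleotideDiversity(al, "all")
  expect_equal(sum(vapply(parts, function(p) p$pi * p$accessible, 0)),
               tot$pi * tot$accessible, tolerance = 1e-10)
})

test_that("Nei-Gojobori site weights follow codon-table enumeration", {
  gl <- classifyCodingSites("GGG")      # glycine: 4-fold third position
  expect_equal(gl$wSyn, c(0, 0, 1))
  met <- classifyCodingSites("ATG")     # Met: everything nonsynonymous
  expect_equal(met$wSyn[1], 0)
  expect_equal(met$wNonsyn[1], 1)
  ile <- classifyCodingSites("ATT")     # Ile: ATC/ATA syn, ATG nonsyn
  expect_equal(ile$wSyn[3], 2 / 3, tolerance = 1e-12)
  amb <- classifyCodingSites("ANT")
  expect_true(all(amb$ambiguous))
  expect_equal(amb$wSyn, c(0, 0, 0))
  expect_warning(classifyCodingSites("TAAGGG"), "stop")
})

test_that("site-spectrum counts follow the allele-count definitions", {
  one <- function(counts) {
    copies <- rep(c("A", "C", "G")[seq_along(counts)], counts)
    SiteAlignment(matrix(copies, ncol = 1))
  }
  sp <- siteSpectrumCounts(one(c(1, 5)))
  expect_equal(sp[c("S", "eta", "etaS")], list(S = 1L, eta = 1L, etaS = 1L))
  sp3 <- siteSpectrumCounts(one(c(1, 1, 4)))
  expect_equal(sp3[c("S", "eta", "etaS")], list(S = 1L, eta = 2L, etaS = 2L))
  mono <- siteSpectrumCounts(SiteAlignment(matrix("A", 7, 12)))
  expect_equal(mono[c("S", "eta", "etaS", "nEff")],
               list(S = 0L, eta = 0L, etaS = 0L, nEff = 7L))
})

test_that("neutrality statistics match the dual-coded oracle on the packaged alignment", {
  al <- readFastaAlignment(f1FixturePath())
  sp <- siteSpectrumCounts(al)
  piSum <- nucleotideDiversity(al)$piSum
  expect_equal(sp$nEff, 6L)
  expect_gt(sp$S, 0)
  expect_equal(tajimasD(sp$nModal, sp$S, piSum),
               oracleTajimaD(sp$nModal, sp$S, piSum), tolerance = 1e-12)
  fl <- fuLiStar(sp$nModal, sp$eta, sp$etaS, piSum)
  or <- oracleFuLi(sp$nModal, sp$eta, sp$etaS, piSum)
  expect_equal(fl$dStar, or$dStar, tolerance = 1e-6)
  expect_equal(fl$fStar, or$fStar, tolerance = 1e-6)

  # undefined sentinels
  expect_true(is.na(tajimasD(10, 0, 0)))
  expect_true(is.na(fuLiStar(10, 0, 0, 0)$dStar))
  expect_true(is.na(tajimasD(3, 5, 2)))
})

test_that("a bottleneck-like excess of intermediate variants drives D positive", {
  # half the copies carry one haplotype, half another, at many sites
  m <- rbind(matrix("A", 10, 30), matrix("T", 10, 30))
  st <- neutralityStats(SiteAlignment(m))
  expect_gt(st$tajimaD, 0)
})

test_that("inbreeding F matches hand-computed homozygosity arithmetic", {
  # three individuals, two sites; both sites at p = 1/2, n = 6 copies
  g <- rbind(c(1L, 2L, 0L),
             c(2L, 0L, 1L))
  F <- inbreedingCoefficient(g)
  eSite <- 1 - 2 * 0.25 * 6 / 5          # expected homozygosity per site
  E <- 2 * eSite
  expect_equal(unname(F), c((1 - E) / (2 - E),   # one hom, one het
                            (2 - E) / (2 - E),   # fully homozygous -> 1
                            (1 - E) / (2 - E)),
               tolerance = 1e-12)

  # direction checks at p = 0.5
  het <- matrix(1L, 20, 4); het[, 2:3] <- rep(c(0L, 2L), each = 10)
  FH <- inbreedingCoefficient(het)
  expect_lt(FH[1], 0)
  hom <- matrix(c(0L, 2L, 0L, 2L), 20, 4, byrow = TRUE)  # p = 0.5, no hets
  expect_gt(inbreedingCoefficient(hom)[1], 0)
})

test_that("pairwise relatedness follows the moment formula and flags clones", {
  # single usable site, both individuals minor homozygous, p = 0.5
  g <- matrix(c(2L, 2L, 0L, 0L), 1, 4)
  a <- pairwiseRelatedness(g)$ajk
  expect_equal(a[1, 2], (2 - 1) * (2 - 1) / 0.5, tolerance = 1e-12)

  # duplicated individual stands out among unrelated ones
  set.seed(104)
  base <- matrix(rbinom(400 * 8, 2, 0.5), 400, 8)
  panel <- cbind(base, clone = base[, 3])
  aj <- pairwiseRelatedness(panel)$ajk
  off <- aj; diag(off) <- NA
  top <- which(off == max(off, na.rm = TRUE), arr.ind = TRUE)[1, ]
  expect_setequal(as.integer(top), c(3L, 9L))
  expect_gt(aj[3, 9], 0.6)

  # an unrelated pair at 1,000 sites hovers near zero; the panel is wide
  # so sample-frequency estimation adds only O(1/N) bias
  g2 <- matrix(rbinom(1000 * 100, 2, 0.5), 1000, 100)
  a2 <- pairwiseRelatedness(g2)$ajk
  expect_lt(abs(a2[1, 2]), 0.1)
})

test_that("region summary derives printed-style percentages and ratios", {
  row <- regionTableRow("All", piSyn = 8.97, piNonsyn = 2.76)
  expect_equal(row$paPs, 0.308)
  expect_equal(regionTableRow("IP", polymorphic = 20680,
                              totalSnps = 25726)$percentPolymorphic,
               round(100 * 20680 / 25726, 2))

  # single-population dataset: overall row equals the region row
  set.seed(105)
  geno <- matrix(rbinom(30 * 10, 2, 0.3), 30, 10)
  ds <- makeDataset(geno, rep("p1", 10))
  tab <- regionSummary(ds, c(p1 = "north"), L = 5000)
  expect_equal(nrow(tab), 2)
  num <- vapply(tab, is.numeric, TRUE)
  expect_equal(unlist(tab[1, num]), unlist(tab[2, num]), tolerance = 1e-12)

  expect_error(regionSummary(ds, c(zz = "north")), "without region")
})
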