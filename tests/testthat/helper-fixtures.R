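# Shared fixture builders. Everything is generated in code; the only file
# fixture is the small synthetic alignment under inst/extdata.

# Random allele matrix with missing copies, for oracle comparisons.
randomAlignment <- function(nCopies, L, missRate = 0.1) {
  m <- matrix(sample(c("A", "C", "G", "T"), nCopies * L, replace = TRUE,
                     prob = c(0.4, 0.3, 0.2, 0.1)),
              nCopies, L)
  m[matrix(runif(nCopies * L) < missRate, nCopies, L)] <- NA_character_
  SiteAlignment(m)
}

# Brute-force nucleotide diversity: mean pairwise per-site difference over
# pairs of copies with both states observed, normalized per accessible site.
bruteForcePi <- function(alignment) {
  al <- alleleMatrix(alignment)
  num <- 0; acc <- 0
  for (j in seq_len(ncol(al))) {
    x <- al[, j][!is.na(al[, j])]
    n <- length(x)
    if (n < 2) next
    acc <- acc + 1
    diffs <- 0; pairs <- 0
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      pairs <- pairs + 1
      diffs <- diffs + (x[a] != x[b])
    }
    num <- num + diffs / pairs
  }
  if (acc == 0) NA_real_ else num / acc
}

# Construct a GeaDataset directly from a genotype matrix, with minimal
# sensible metadata; per-SNP fields can be overridden.
makeDataset <- function(geno, pops, gene = NULL, coverage = 50,
                        alleleBalance = 0.5, nAlleles = 2L,
                        climate = NULL, externalCalls = data.frame()) {
  nSnp <- nrow(geno)
  if (is.null(rownames(geno))) rownames(geno) <- sprintf("s%03d", 1:nSnp)
  if (is.null(colnames(geno)))
    colnames(geno) <- sprintf("ind%02d", seq_len(ncol(geno)))
  if (is.null(gene)) gene <- rep("g1", nSnp)
  meta <- data.frame(
    snp = rownames(geno), chrom = gene, pos = seq_len(nSnp),
    ref = "A", alt = "T", minorAllele = "T",
    nAlleles = rep_len(nAlleles, nSnp),
    coverage = rep_len(coverage, nSnp),
    alleleBalance = rep_len(alleleBalance, nSnp),
    missingFrac = rowMeans(is.na(geno)),
    gene = gene, siteClass = "other", stringsAsFactors = FALSE)
  if (is.null(names(pops))) names(pops) <- colnames(geno)
  if (is.null(climate)) climate <- matrix(numeric(0), 0, 0)
  GeaDataset(geno, meta, pops, climate = climate,
             externalCalls = externalCalls)
}

# Independently coded Tajima's D oracle (constant by constant).
oracleTajimaD <- function(n, S, piSum) {
  if (S < 1 || n < 4) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (piSum - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

# Independently coded Fu & Li D*/F* oracle with the corrected coefficients.
oracleFuLi <- function(n, eta, etaS, piSum) {
  if (eta < 1 || n < 4) return(list(dStar = NA, fStar = NA))
  an <- sum(1 / seq_len(n - 1)); bn <- sum(1 / seq_len(n - 1)^2)
  an1 <- an + 1 / n
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    2 / (n - 1) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * bn + an^2 * dn -
         2 * n * an * (an + 1) / (n - 1)^2) / (an^2 + bn)
  uD <- n / (n - 1) * (an - n / (n - 1)) - vD
  vF <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
         2 * (n - 1) * an / n^2 - 8 * bn / n) / (an^2 + bn)
  uF <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * an1) /
         (3 * n * (n - 1))) / an - vF
  list(dStar = (n / (n - 1) * eta - an * etaS) /
         sqrt(uD * eta + vD * eta^2),
       fStar = (piSum - (n - 1) / n * etaS) / sqrt(uF * eta + vF * eta^2))
}

f1FixturePath <- function() {
  system.file("extdata", "F1_synthetic.fasta", package = "adaptscan")
}
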