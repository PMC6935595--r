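## SNP filter cascade. A SNP failing several rules is attributed to the
## first failing rule in the fixed order (biallelic, polymorphic,
## missingness, coverage, allele balance), so reports are deterministic and
## removed counts sum to input - surviving.

#' Filter SNPs on biallelism, polymorphism, missingness, coverage and
#' allele balance
#'
#' Keeps polymorphic biallelic SNPs with a missing-genotype fraction below
#' \code{maxMissing}, mean coverage inside \code{coverageRange} (closed
#' interval) and heterozygote allele balance inside \code{alleleBalance}
#' (closed interval). Coverage and allele-balance rules are skipped with a
#' warning when the corresponding metadata column is entirely absent; a SNP
#' with no heterozygous calls has undefined allele balance and passes that
#' rule.
#'
#' @param ds a [GeaDataset-class].
#' @param coverageRange numeric length-2, inclusive mean-coverage bounds.
#' @param alleleBalance numeric length-2, inclusive bounds for the mean
#'   alternate-read fraction of heterozygous calls.
#' @param maxMissing maximum tolerated missing-genotype fraction (strict).
#' @param biallelicOnly drop SNPs with more than two observed alleles.
#' @return list with elements \code{dataset} (filtered [GeaDataset-class])
#'   and \code{report} (named list: per-rule removal counts, \code{surviving},
#'   \code{input}, \code{params}).
#' @export
filterSites <- function(ds, coverageRange = c(20, 250),
                        alleleBalance = c(0.3, 0.7),
                        maxMissing = 0.15, biallelicOnly = TRUE) {
  g <- genotypes(ds)
  m <- snpMeta(ds)
  n <- nrow(g)

  nMiss <- rowSums(is.na(g))
  nObs <- ncol(g) - nMiss
  copySum <- rowSums(g, na.rm = TRUE)
  polymorphic <- nObs > 0 & copySum > 0L & copySum < 2L * nObs
  biallelic <- if ("nAlleles" %in% names(m)) m$nAlleles <= 2 else
    rep(TRUE, n)
  missOk <- nMiss / ncol(g) < maxMissing

  covOk <- rep(TRUE, n)
  haveCov <- "coverage" %in% names(m) && !all(is.na(m$coverage))
  if (haveCov) {
    covOk <- is.na(m$coverage) |
      (m$coverage >= coverageRange[1] & m$coverage <= coverageRange[2])
  } else warning("no coverage metadata; coverage rule skipped")

  abOk <- rep(TRUE, n)
  haveAb <- "alleleBalance" %in% names(m) && !all(is.na(m$alleleBalance))
  if (haveAb) {
    abOk <- is.na(m$alleleBalance) |
      (m$alleleBalance >= alleleBalance[1] &
       m$alleleBalance <= alleleBalance[2])
  } else warning("no allele-balance metadata; allele-balance rule skipped")

  ## first-failing-rule attribution
  rule <- rep("pass", n)
  rule[!abOk] <- "allele_balance"
  rule[!covOk] <- "coverage"
  rule[!missOk] <- "missingness"
  rule[!polymorphic] <- "not_polymorphic"
  if (biallelicOnly) rule[!biallelic] <- "not_biallelic"

  keep <- rule == "pass"
  report <- list(
    not_biallelic = sum(rule == "not_biallelic"),
    not_polymorphic = sum(rule == "not_polymorphic"),
    missingness = sum(rule == "missingness"),
    coverage = sum(rule == "coverage"),
    allele_balance = sum(rule == "allele_balance"),
    surviving = sum(keep),
    input = n,
    params = list(coverageRange = coverageRange,
                  alleleBalance = alleleBalance,
                  maxMissing = maxMissing,
                  biallelicOnly = biallelicOnly))
  if (!any(keep)) warning("no SNPs survive the filter chain")
  list(dataset = ds[keep, ], report = report)
}

## cache of conditional heterozygote-count distributions keyed by "n.nA"
.hweCache <- new.env(parent = emptyenv())

#' Exact one-sided Hardy-Weinberg heterozygote-excess p-value
#'
#' Conditional on the observed allele counts (\code{nA} copies of one allele
#' among \code{2n} copies in \code{n} diploids), heterozygote counts with the
#' parity of \code{nA} are enumerated under the exact Hardy-Weinberg
#' (Levene) distribution, and the upper tail at the observed count is
#' returned: \eqn{p = P(H \ge h_{obs})}.
#'
#' @param nHet observed heterozygote count.
#' @param nA copies of the focal (e.g. minor) allele among genotyped
#'   individuals.
#' @param n number of genotyped diploids.
#' @return one-sided p-value for heterozygote excess; 1 for monomorphic
#'   samples; \code{NA} when \code{n < 2} (not testable).
#' @examples
#' hweExcessTest(10, 10, 10)  # all ten diploids heterozygous
#' @export
hweExcessTest <- function(nHet, nA, n) {
  if (n < 2) return(NA_real_)
  nA <- min(nA, 2 * n - nA)
  if (nA == 0) return(1)
  key <- paste(n, nA, sep = ".")
  dist <- .hweCache[[key]]
  if (is.null(dist)) {
    h <- seq(nA %% 2L, min(nA, 2L * n - nA), by = 2L)
    nAA <- (nA - h) / 2
    nBB <- n - nAA - h
    logp <- lgamma(n + 1) - lgamma(nAA + 1) - lgamma(h + 1) -
      lgamma(nBB + 1) + h * log(2) +
      lgamma(nA + 1) + lgamma(2 * n - nA + 1) - lgamma(2 * n + 1)
    p <- exp(logp)
    dist <- list(h = h, p = p / sum(p))
    .hweCache[[key]] <- dist
  }
  sum(dist$p[dist$h >= nHet])
}

#' Remove SNPs with significant heterozygote excess in multiple populations
#'
#' Screens for putative paralogs: for every SNP and population the exact
#' one-sided heterozygote-excess test ([hweExcessTest()]) is applied to the
#' genotyped individuals of that population, and the SNP is removed when the
#' test is significant (\eqn{p \le \alpha}) in at least
#' \code{minPopulations} populations. Populations with fewer than two
#' genotyped individuals are not testable and never count as significant.
#'
#' @param ds a [GeaDataset-class].
#' @param alpha per-population significance level.
#' @param minPopulations minimum number of significant populations for
#'   removal.
#' @return list with elements \code{dataset} (filtered), \code{report}
#'   (removal count and parameters) and \code{nSignif} (per-SNP count of
#'   significant populations).
#' @export
hetExcessFilter <- function(ds, alpha = 0.05, minPopulations = 4L) {
  g <- genotypes(ds)
  pops <- popmap(ds)
  bySamp <- split(colnames(g), pops[colnames(g)])
  nSig <- integer(nrow(g))
  for (samps in bySamp) {
    sub <- g[, samps, drop = FALSE]
    nObs <- rowSums(!is.na(sub))
    nHet <- rowSums(sub == 1L, na.rm = TRUE)
    nA <- rowSums(sub, na.rm = TRUE)
    p <- vapply(seq_len(nrow(sub)), function(i)
      hweExcessTest(nHet[i], nA[i], nObs[i]), 0)
    nSig <- nSig + (!is.na(p) & p <= alpha)
  }
  keep <- nSig < minPopulations
  report <- list(het_excess = sum(!keep), surviving = sum(keep),
                 input = nrow(g),
                 params = list(alpha = alpha,
                               minPopulations = minPopulations))
  list(dataset = ds[keep, ], report = report, nSignif = nSig)
}
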