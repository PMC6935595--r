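## Sequence diversity from per-gene allele matrices. All statistics are
## frequency-based and operate on the 2N unphased allele copies per site;
## missing copies reduce the per-site sample size n_j, and sites with
## n_j < 2 are excluded from both numerator and denominator.

#' Per-site heterozygosity of every site in an alignment
#'
#' For a site with \eqn{n_j \ge 2} non-missing copies and allele counts
#' \eqn{c_a}, returns \eqn{h_j = n_j/(n_j-1)\,(1 - \sum_a (c_a/n_j)^2)},
#' which equals the mean pairwise difference among the non-missing copies.
#' Sites with fewer than two copies get \code{NA}.
#'
#' @param alignment a [SiteAlignment-class].
#' @return numeric vector of length L.
#' @export
perSiteHeterozygosity <- function(alignment) {
  al <- alleleMatrix(alignment)
  vapply(seq_len(ncol(al)), function(j) {
    x <- al[, j]
    x <- x[!is.na(x)]
    n <- length(x)
    if (n < 2) return(NA_real_)
    cts <- tabulate(match(x, unique(x)))
    n / (n - 1) * (1 - sum((cts / n)^2))
  }, 0)
}

#' Nucleotide diversity per site, by site class
#'
#' Class diversity is the weighted mean of per-site heterozygosity
#' ([perSiteHeterozygosity()]) over all sites with at least two non-missing
#' copies, monomorphic sites included: \eqn{\pi_c = \sum_j h_j w_j(c) /
#' \sum_j w_j(c)}. The denominator is the accessible site total for the
#' class, so values are per base pair.
#'
#' @param alignment a [SiteAlignment-class].
#' @param class one of \code{"all"}, \code{"syn"}, \code{"nonsyn"},
#'   \code{"other"}.
#' @return named list: \code{pi} (per-site diversity; \code{NA} when the
#'   class has zero accessible sites), \code{accessible} (weighted site
#'   total), \code{piSum} (weighted heterozygosity sum).
#' @examples
#' al <- SiteAlignment(matrix(c("A", "A", "T", "T"), 4, 1))
#' nucleotideDiversity(al)$pi  # (4/3) * (1 - 1/2) = 2/3
#' @export
nucleotideDiversity <- function(alignment,
                                class = c("all", "syn", "nonsyn", "other")) {
  class <- match.arg(class)
  h <- perSiteHeterozygosity(alignment)
  w <- if (class == "all") rep(1, length(h))
       else siteWeights(alignment)[, class]
  ok <- !is.na(h)
  acc <- sum(w[ok])
  piSum <- sum(h[ok] * w[ok])
  list(pi = if (acc > 0) piSum / acc else NA_real_,
       accessible = acc, piSum = piSum)
}

#' Segregating-site and mutation counts of an alignment
#'
#' @param alignment a [SiteAlignment-class].
#' @return named list: \code{S} sites with two or more alleles among
#'   non-missing copies; \code{eta} total mutations, the infinite-sites
#'   minimum \eqn{\sum_j(\mathrm{alleles}_j - 1)}; \code{etaS} singleton
#'   mutations, counting every allele observed in exactly one copy;
#'   \code{nEff} the maximum per-site number of non-missing copies;
#'   \code{nModal} the modal per-site number of non-missing copies.
#' @export
siteSpectrumCounts <- function(alignment) {
  al <- alleleMatrix(alignment)
  S <- 0L; eta <- 0L; etaS <- 0L
  nVec <- rep(NA_integer_, ncol(al))
  for (j in seq_len(ncol(al))) {
    x <- al[, j]
    x <- x[!is.na(x)]
    if (!length(x)) next
    nVec[j] <- length(x)
    cts <- tabulate(match(x, unique(x)))
    k <- length(cts)
    if (k >= 2) {
      S <- S + 1L
      eta <- eta + (k - 1L)
      etaS <- etaS + sum(cts == 1L)
    }
  }
  nVec <- nVec[!is.na(nVec)]
  nEff <- if (length(nVec)) max(nVec) else 0L
  nModal <- if (length(nVec)) {
    tb <- tabulate(nVec)
    which.max(tb)
  } else 0L
  list(S = S, eta = eta, etaS = etaS, nEff = nEff, nModal = nModal)
}

#' Full diversity summary of one gene alignment
#'
#' Combines per-class nucleotide diversity, the site-spectrum counts and
#' the nonsynonymous-to-synonymous diversity ratio.
#'
#' @param alignment a [SiteAlignment-class].
#' @return named list with \code{piAll}, \code{piSyn}, \code{piNonsyn},
#'   \code{paPs} (\code{NA} when \eqn{\pi_s = 0} or undefined), the
#'   accessible site totals per class, and the [siteSpectrumCounts()]
#'   fields.
#' @export
diversityStats <- function(alignment) {
  all <- nucleotideDiversity(alignment, "all")
  syn <- nucleotideDiversity(alignment, "syn")
  non <- nucleotideDiversity(alignment, "nonsyn")
  sp <- siteSpectrumCounts(alignment)
  paPs <- if (!is.na(syn$pi) && syn$pi > 0 && !is.na(non$pi))
    non$pi / syn$pi else NA_real_
  c(list(piAll = all$pi, piSyn = syn$pi, piNonsyn = non$pi, paPs = paPs,
         accessibleAll = all$accessible, accessibleSyn = syn$accessible,
         accessibleNonsyn = non$accessible, piSum = all$piSum), sp)
}

#' Nei-Gojobori fractional synonymous site weights of a coding sequence
#'
#' For every position of an in-frame coding sequence, enumerates the three
#' possible single-base changes at that codon position and returns the
#' fraction that leave the encoded amino acid unchanged (\code{wSyn});
#' changes creating a stop codon count as nonsynonymous. Codons containing
#' characters outside A/C/G/T are flagged and receive zero coding weight
#' (all weight on \code{other}).
#'
#' @param cds character scalar or vector of single bases, the coding
#'   sequence.
#' @param frame offset (0, 1 or 2) of the first complete codon.
#' @param geneticCode named character vector mapping codons to amino acids;
#'   defaults to the standard code.
#' @return data.frame with one row per site inside a complete codon:
#'   \code{pos}, \code{codon}, \code{codonPos}, \code{wSyn}, \code{wNonsyn},
#'   \code{ambiguous}.
#' @examples
#' classifyCodingSites("GGG")$wSyn   # 0, 0, 1 (4-fold third position)
#' @export
classifyCodingSites <- function(cds, frame = 0L,
                                geneticCode = standardGeneticCode()) {
  bases <- if (length(cds) == 1L) strsplit(toupper(cds), "")[[1]]
           else toupper(cds)
  usable <- bases[(frame + 1L):length(bases)]
  nCodon <- length(usable) %/% 3L
  if (length(usable) %% 3L != 0L)
    warning("sequence length after frame offset not divisible by 3; ",
            "trailing bases ignored")
  out <- vector("list", nCodon)
  nt <- c("A", "C", "G", "T")
  for (ci in seq_len(nCodon)) {
    codon <- usable[(3L * ci - 2L):(3L * ci)]
    amb <- !all(codon %in% nt)
    codStr <- paste(codon, collapse = "")
    aa <- if (amb) NA_character_ else geneticCode[[codStr]]
    if (!amb && aa == "*" && ci < nCodon)
      warning("internal stop codon at codon ", ci)
    wSyn <- numeric(3)
    if (!amb) {
      for (p in 1:3) {
        alt <- setdiff(nt, codon[p])
        syn <- vapply(alt, function(b) {
          mut <- codon; mut[p] <- b
          mutAa <- geneticCode[[paste(mut, collapse = "")]]
          mutAa != "*" && mutAa == aa
        }, TRUE)
        wSyn[p] <- mean(syn)
      }
    }
    out[[ci]] <- data.frame(
      pos = frame + (3L * ci - 2L):(3L * ci),
      codon = codStr, codonPos = 1:3,
      wSyn = if (amb) 0 else wSyn,
      wNonsyn = if (amb) 0 else 1 - wSyn,
      ambiguous = amb)
  }
  do.call(rbind, out)
}

#' The standard genetic code as a codon-to-amino-acid map
#' @return named character vector of length 64 ("*" marks stops).
#' @export
standardGeneticCode <- function() {
  nt <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- character(64); k <- 0L
  for (b1 in nt) for (b2 in nt) for (b3 in nt) {
    k <- k + 1L; codons[k] <- paste0(b1, b2, b3)
  }
  setNames(aa, codons)
}
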