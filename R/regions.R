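## Region-level summary table of diversity, neutrality and inbreeding
## statistics, mirroring the usual "per geographic region plus overall"
## report from concatenated target-capture panels.

#' One summary row from region-level counts and diversities
#'
#' Derives the reported quantities from their inputs: the percentage of
#' polymorphic sites relative to the full SNP panel (2 decimals) and the
#' nonsynonymous-to-synonymous diversity ratio (3 decimals, \code{NA} when
#' \eqn{\pi_s} is zero or missing). Diversities are reported on the
#' per-site x 10^-3 scale when supplied that way; the row performs no
#' rescaling.
#'
#' @param region region label.
#' @param nInd number of individuals.
#' @param L total sequence length in bp (\code{NA} allowed).
#' @param polymorphic number of polymorphic sites in the region.
#' @param totalSnps size of the full SNP panel.
#' @param piAll,piSyn,piNonsyn per-site diversities.
#' @param tajimaD,dStar,fStar,meanF,meanAjk optional statistics carried
#'   through unchanged.
#' @return one-row data.frame with the derived \code{percentPolymorphic}
#'   and \code{paPs} columns.
#' @export
regionTableRow <- function(region, nInd = NA, L = NA, polymorphic = NA,
                           totalSnps = NA, piAll = NA, piSyn = NA,
                           piNonsyn = NA, tajimaD = NA, dStar = NA,
                           fStar = NA, meanF = NA, meanAjk = NA) {
  pct <- if (!is.na(polymorphic) && !is.na(totalSnps) && totalSnps > 0)
    round(100 * polymorphic / totalSnps, 2) else NA_real_
  paPs <- if (!is.na(piSyn) && !is.na(piNonsyn) && piSyn > 0)
    round(piNonsyn / piSyn, 3) else NA_real_
  data.frame(region = region, nInd = nInd, L = L,
             polymorphic = polymorphic,
             percentPolymorphic = pct,
             piAll = piAll, piSyn = piSyn, piNonsyn = piNonsyn,
             paPs = paPs, tajimaD = tajimaD, dStar = dStar, fStar = fStar,
             meanF = meanF, meanAjk = meanAjk,
             stringsAsFactors = FALSE)
}

#' Region-level statistics from a SNP genotype panel
#'
#' Computes, per region and for all samples pooled (the \code{"All"} row):
#' the polymorphic-SNP count and its percentage of the full panel, summed
#' pairwise heterozygosity converted to per-site diversity over \code{L}
#' (overall and by site class, using per-class accessible totals when
#' supplied), the neutrality tests with n taken as the modal per-SNP
#' non-missing copy count, and mean inbreeding F and mean off-diagonal
#' relatedness. Diversities are reported x 10^-3 per site.
#'
#' @param ds a [GeaDataset-class]; \code{snpMeta(ds)$siteClass} supplies
#'   the per-SNP site class (\code{syn}/\code{nonsyn}/\code{other}).
#' @param regions named character vector, population -> region. Populations
#'   left unmapped raise an error.
#' @param L total accessible length (bp) per region, a single value or a
#'   named vector by region; \code{NA} leaves per-site diversities
#'   undefined.
#' @param accessible optional named list with per-class accessible site
#'   totals \code{syn} and \code{nonsyn} (single values or named vectors by
#'   region).
#' @return data.frame of [regionTableRow()] rows, one per region plus
#'   \code{"All"}.
#' @export
regionSummary <- function(ds, regions, L = NA, accessible = NULL) {
  pm <- popmap(ds)
  unmapped <- setdiff(unique(pm), names(regions))
  if (length(unmapped))
    stop("population(s) without region: ", paste(unmapped, collapse = ", "))
  g <- genotypes(ds)
  cls <- snpMeta(ds)$siteClass
  if (is.null(cls)) cls <- rep("other", nrow(g))
  sampleRegion <- regions[pm[colnames(g)]]

  pick <- function(v, region) {
    if (is.null(v)) return(NA_real_)
    if (length(v) == 1L && is.null(names(v))) return(as.numeric(v))
    if (!is.null(names(v)) && region %in% names(v))
      return(as.numeric(v[[region]]))
    as.numeric(v[[1L]])
  }

  oneRegion <- function(label, samples) {
    sub <- g[, samples, drop = FALSE]
    nObs <- rowSums(!is.na(sub))
    cnt <- rowSums(sub, na.rm = TRUE)
    poly <- nObs > 0 & cnt > 0L & cnt < 2L * nObs
    nc <- 2L * nObs
    h <- ifelse(nc >= 2,
                nc / (nc - 1) *
                  (1 - (cnt / nc)^2 - ((nc - cnt) / nc)^2), NA_real_)
    ok <- !is.na(h)
    Lr <- pick(L, label)
    accS <- pick(accessible$syn, label)
    accN <- pick(accessible$nonsyn, label)
    ## heterozygosity sums by class; monomorphic target sites contribute 0
    piSum <- sum(h[ok])
    piSumSyn <- sum(h[ok & cls == "syn"])
    piSumNon <- sum(h[ok & cls == "nonsyn"])
    piAll <- if (!is.na(Lr)) 1e3 * piSum / Lr else NA_real_
    piSyn <- if (!is.na(accS)) 1e3 * piSumSyn / accS else NA_real_
    piNon <- if (!is.na(accN)) 1e3 * piSumNon / accN else NA_real_
    ## neutrality inputs on the SNP panel (biallelic sites: eta = S)
    nModal <- {
      tb <- table(nc[nc >= 2])
      if (length(tb)) as.integer(names(tb)[which.max(tb)]) else 0L
    }
    S <- sum(poly)
    etaS <- sum(poly & (cnt == 1L | cnt == nc - 1L))
    fl <- fuLiStar(nModal, S, etaS, piSum)
    Fk <- inbreedingCoefficient(sub)
    aj <- pairwiseRelatedness(sub)$ajk
    off <- aj[upper.tri(aj)]
    regionTableRow(label, nInd = length(samples), L = Lr,
                   polymorphic = S, totalSnps = nrow(g),
                   piAll = piAll, piSyn = piSyn, piNonsyn = piNon,
                   tajimaD = tajimasD(nModal, S, piSum),
                   dStar = fl$dStar, fStar = fl$fStar,
                   meanF = mean(Fk, na.rm = TRUE),
                   meanAjk = mean(off, na.rm = TRUE))
  }

  labs <- unique(regions[pm[colnames(g)]])
  rows <- lapply(labs, function(r)
    oneRegion(r, colnames(g)[sampleRegion == r]))
  rows <- c(rows, list(oneRegion("All", colnames(g))))
  do.call(rbind, rows)
}
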