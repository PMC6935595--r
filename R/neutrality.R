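## Frequency-spectrum neutrality tests. The classical formulas assume a
## fixed sample size n of allele copies; with missing data the per-gene n
## is taken as the modal (default) or maximum per-site non-missing copy
## count, and the choice is recorded by the caller.

#' Harmonic-number coefficients shared by the neutrality tests
#' @noRd
.harm <- function(n) {
  i <- seq_len(n - 1)
  list(a1 = sum(1 / i), a2 = sum(1 / i^2))
}

#' Tajima's D
#'
#' Normalized difference between the pairwise-diversity estimator of theta
#' (\code{piSum}, the sum of per-site mean pairwise differences over all
#' sites) and the Watterson estimator \eqn{S/a_1}.
#'
#' @param n number of allele copies (>= 4).
#' @param S number of segregating sites.
#' @param piSum sum of per-site heterozygosity \eqn{h_j} over all sites.
#' @return Tajima's D, or \code{NA} when \code{S == 0} or \code{n < 4}.
#' @references Tajima (1989) Genetics 123:585-595.
#' @export
tajimasD <- function(n, S, piSum) {
  if (is.na(S) || S < 1 || n < 4) return(NA_real_)
  h <- .harm(n)
  a1 <- h$a1; a2 <- h$a2
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (piSum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Fu and Li's D* and F* (no outgroup)
#'
#' Starred statistics contrasting singleton mutations with total mutations
#' (D*) or with pairwise diversity (F*). Coefficients use the corrected
#' expressions adopted by mainstream implementations; the originally
#' published ones contain documented typographical errors.
#'
#' @param n number of allele copies (>= 4).
#' @param eta total number of mutations (\eqn{\sum_j(\mathrm{alleles}_j-1)}).
#' @param etaS number of singleton mutations (alleles seen in one copy).
#' @param piSum sum of per-site heterozygosity over all sites.
#' @return named list \code{dStar}, \code{fStar}; both \code{NA} when
#'   \code{eta == 0} or \code{n < 4}.
#' @references Fu and Li (1993) Genetics 133:693-709; Simonsen, Churchill
#'   and Aquadro (1995) Genetics 141:413-429.
#' @export
fuLiStar <- function(n, eta, etaS, piSum) {
  if (is.na(eta) || eta < 1 || n < 4)
    return(list(dStar = NA_real_, fStar = NA_real_))
  h <- .harm(n)
  an <- h$a1; bn <- h$a2
  an1 <- an + 1 / n

  cn <- if (n == 2) 1 else 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)

  vD <- ((n / (n - 1))^2 * bn + an^2 * dn -
         2 * (n * an * (an + 1)) / (n - 1)^2) / (an^2 + bn)
  uD <- (n / (n - 1)) * (an - n / (n - 1)) - vD
  dStar <- ((n / (n - 1)) * eta - an * etaS) /
    sqrt(uD * eta + vD * eta^2)

  vF <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
         (2 * (n - 1) * an) / n^2 - 8 * bn / n) / (an^2 + bn)
  uF <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * an1) /
         (3 * n * (n - 1))) / an - vF
  fStar <- (piSum - ((n - 1) / n) * etaS) / sqrt(uF * eta + vF * eta^2)

  list(dStar = dStar, fStar = fStar)
}

#' Neutrality tests for one gene alignment
#'
#' Computes the site-spectrum inputs from a [SiteAlignment-class] and
#' applies [tajimasD()] and [fuLiStar()]. With missing data the fixed
#' sample size required by the formulas is taken as the modal (default) or
#' maximum per-site non-missing copy count.
#'
#' @param alignment a [SiteAlignment-class].
#' @param nMode \code{"modal"} or \code{"max"}.
#' @return named list \code{tajimaD}, \code{dStar}, \code{fStar}, \code{n},
#'   plus the [siteSpectrumCounts()] fields.
#' @export
neutralityStats <- function(alignment, nMode = c("modal", "max")) {
  nMode <- match.arg(nMode)
  sp <- siteSpectrumCounts(alignment)
  piSum <- nucleotideDiversity(alignment, "all")$piSum
  n <- if (nMode == "modal") sp$nModal else sp$nEff
  fl <- fuLiStar(n, sp$eta, sp$etaS, piSum)
  c(list(tajimaD = tajimasD(n, sp$S, piSum),
         dStar = fl$dStar, fStar = fl$fStar, n = n, piSum = piSum), sp)
}
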