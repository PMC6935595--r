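## Method-of-moments inbreeding and relatedness from the SNP genotype
## matrix (minor-allele copy counts). Raw values are reported without
## clipping, matching the usual unadjusted estimators.

#' Per-individual method-of-moments inbreeding coefficient
#'
#' \eqn{F = (O_{hom} - E_{hom}) / (M - E_{hom})} over the individual's M
#' non-missing sites, with the expected homozygosity per site
#' \eqn{1 - 2 p_j (1-p_j)\, n_j/(n_j-1)} computed from the sample allele
#' frequency \eqn{p_j} and the number of non-missing copies \eqn{n_j}.
#'
#' @param geno integer SNP x sample matrix of allele-copy counts (0/1/2,
#'   \code{NA} missing).
#' @return named numeric vector of F per individual; \code{NA} when the
#'   denominator vanishes (no informative sites).
#' @export
inbreedingCoefficient <- function(geno) {
  geno <- as.matrix(geno)
  nCopies <- 2 * rowSums(!is.na(geno))
  p <- rowSums(geno, na.rm = TRUE) / nCopies
  eSite <- 1 - 2 * p * (1 - p) * nCopies / (nCopies - 1)
  eSite[nCopies < 2] <- NA
  vapply(seq_len(ncol(geno)), function(k) {
    ok <- !is.na(geno[, k]) & !is.na(eSite)
    M <- sum(ok)
    if (M == 0) return(NA_real_)
    O <- sum(geno[ok, k] != 1L)
    E <- sum(eSite[ok])
    if (abs(M - E) < .Machine$double.eps * M) return(NA_real_)
    (O - E) / (M - E)
  }, 0) |> setNames(colnames(geno))
}

#' Pairwise relatedness (unadjusted A_jk) and its diagonal
#'
#' Yang et al.'s genetic-relationship estimator: for individuals j != k,
#' \eqn{A_{jk} = M^{-1} \sum_i (x_{ij} - 2p_i)(x_{ik} - 2p_i) /
#' (2 p_i (1-p_i))}; the diagonal is \eqn{1 + M^{-1}\sum_i (x_{ij}^2 -
#' (1+2p_i)x_{ij} + 2p_i^2) / (2p_i(1-p_i))}. Sites that are monomorphic
#' (\eqn{p_i \in \{0,1\}}) or missing in either member of a pair are
#' excluded from that pair's M. Values near zero indicate unrelated
#' individuals; duplicated samples (clones) stand out with values above
#' ~0.6.
#'
#' @param geno integer SNP x sample matrix of allele-copy counts.
#' @return list with \code{ajk} (symmetric N x N matrix; entries \code{NA}
#'   when a pair shares no usable site) and \code{M} (matrix of per-pair
#'   usable site counts).
#' @references Yang et al. (2010) Nature Genetics 42:565-569.
#' @export
pairwiseRelatedness <- function(geno) {
  geno <- as.matrix(geno)
  nCopies <- 2 * rowSums(!is.na(geno))
  p <- rowSums(geno, na.rm = TRUE) / nCopies
  usable <- nCopies >= 2 & p > 0 & p < 1
  g <- geno[usable, , drop = FALSE]
  p <- p[usable]
  denom <- 2 * p * (1 - p)

  z <- (g - 2 * p) / sqrt(denom)      # standardized scores, NA if missing
  zz <- z; zz[is.na(zz)] <- 0
  obs <- !is.na(z)
  num <- crossprod(zz)
  M <- crossprod(obs)
  ajk <- num / M
  ajk[M == 0] <- NA

  ## diagonal: 1 + mean over own non-missing usable sites
  diagTerm <- (g^2 - (1 + 2 * p) * g + 2 * p^2) / denom
  dT <- diagTerm; dT[is.na(dT)] <- 0
  Mk <- colSums(obs)
  diag(ajk) <- 1 + colSums(dT) / Mk
  diag(ajk)[Mk == 0] <- NA
  dimnames(ajk) <- list(colnames(geno), colnames(geno))
  list(ajk = ajk, M = M)
}
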