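## SNP-level climate scans, the gene-level binomial outlier test, and the
## top-candidate combination rule with external association calls.

#' Per-population minor-allele frequencies
#'
#' @param ds a [GeaDataset-class].
#' @return list with \code{freq} (SNP x population matrix of minor-allele
#'   frequencies; \code{NA} where a population has no genotyped copies) and
#'   \code{copies} (matrix of non-missing allele-copy counts used).
#' @export
populationAlleleFrequencies <- function(ds) {
  g <- genotypes(ds)
  pm <- popmap(ds)
  pops <- unique(pm[colnames(g)])
  freq <- matrix(NA_real_, nrow(g), length(pops),
                 dimnames = list(rownames(g), pops))
  copies <- matrix(0L, nrow(g), length(pops),
                   dimnames = list(rownames(g), pops))
  for (p in pops) {
    sub <- g[, pm[colnames(g)] == p, drop = FALSE]
    nc <- 2L * rowSums(!is.na(sub))
    cnt <- rowSums(sub, na.rm = TRUE)
    freq[, p] <- ifelse(nc > 0, cnt / nc, NA_real_)
    copies[, p] <- nc
  }
  list(freq = freq, copies = copies)
}

#' Spearman rank-correlation p-value via the t approximation
#' @noRd
.spearmanRhoP <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  m <- sum(ok)
  if (m < 4) return(c(rho = NA, p = NA, m = m))
  rx <- rank(x[ok]); ry <- rank(y[ok])
  if (var(rx) == 0 || var(ry) == 0) return(c(rho = NA, p = NA, m = m))
  rho <- cor(rx, ry)
  p <- if (abs(rho) >= 1 - 1e-12) 0 else
    2 * pt(abs(rho) * sqrt((m - 2) / (1 - rho^2)), m - 2,
           lower.tail = FALSE)
  c(rho = rho, p = p, m = m)
}

#' Scan SNP allele frequencies against climate variables by rank
#' correlation
#'
#' For every SNP and every climate column (variable x period), computes
#' Spearman's rho (Pearson correlation of mid-ranks, average ranks on
#' ties) between the per-population minor-allele frequencies and the
#' climate values, with a two-sided p-value from the t approximation
#' \eqn{t = \rho\sqrt{(m-2)/(1-\rho^2)}} on \eqn{m-2} degrees of freedom
#' (\eqn{|\rho| = 1} maps to \eqn{p = 0}). Pairs with fewer than four
#' populations of data, or zero variance in either vector, are emitted as
#' untested (\code{NA} rho and p, \code{significant = FALSE}).
#'
#' @param freqs result of [populationAlleleFrequencies()] (or a plain SNP x
#'   population frequency matrix).
#' @param climate population x column climate matrix with columns named
#'   \code{"<variable>_<period>"} (see [climateMatrix()]).
#' @param alpha significance level (default 0.01).
#' @return data.frame with columns \code{snp}, \code{variable},
#'   \code{period}, \code{rho}, \code{p}, \code{m}, \code{significant}; the
#'   threshold used is stored in \code{attr(, "alpha")}.
#' @export
spearmanScan <- function(freqs, climate, alpha = 0.01) {
  f <- if (is.list(freqs)) freqs$freq else freqs
  pops <- intersect(colnames(f), rownames(climate))
  if (length(pops) < 4)
    stop("fewer than 4 populations shared between frequencies and climate")
  f <- f[, pops, drop = FALSE]
  cl <- climate[pops, , drop = FALSE]
  cols <- colnames(cl)
  vp <- strsplit(cols, "_(?=[^_]+$)", perl = TRUE)
  out <- vector("list", length(cols))
  for (j in seq_along(cols)) {
    res <- t(vapply(seq_len(nrow(f)), function(i)
      .spearmanRhoP(f[i, ], cl[, j]), c(rho = 0, p = 0, m = 0)))
    out[[j]] <- data.frame(
      snp = rownames(f),
      variable = vp[[j]][1], period = vp[[j]][2],
      rho = res[, "rho"], p = res[, "p"], m = as.integer(res[, "m"]),
      significant = !is.na(res[, "p"]) & res[, "p"] < alpha,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "alpha") <- alpha
  res
}

#' Gene-level binomial outlier test for an excess of climate-associated
#' SNPs
#'
#' For each climate column separately, counts per gene the total SNPs
#' tested (\eqn{n_i}) and those significantly associated (\eqn{a_i}),
#' estimates the expected per-SNP rate P over the genes with at least one
#' significant SNP, and flags genes whose \eqn{a_i} exceeds the 0.9999
#' quantile of Binomial(\eqn{n_i}, P). Genes with zero significant SNPs
#' are excluded from the estimate of P (they cannot be flagged) but are
#' still reported so totals reconcile.
#'
#' @param assoc data.frame from [spearmanScan()].
#' @param geneMap named character vector snp -> gene, or a data.frame with
#'   columns \code{snp} and \code{gene}.
#' @param quantile binomial quantile defining the outlier threshold.
#' @param poolRule \code{"pooled"} (default): \eqn{P = \sum_i a_i / \sum_i
#'   n_i}; \code{"mean-ratio"}: mean of per-gene \eqn{a_i/n_i}.
#' @return data.frame with columns \code{gene}, \code{variable},
#'   \code{period}, \code{n}, \code{a}, \code{P}, \code{qThreshold},
#'   \code{flagged}. Zero rows (with attribute \code{status =
#'   "inapplicable"}) when no gene has a significant SNP.
#' @export
geneOutlierTest <- function(assoc, geneMap, quantile = 0.9999,
                            poolRule = c("pooled", "mean-ratio")) {
  poolRule <- match.arg(poolRule)
  if (is.data.frame(geneMap))
    geneMap <- setNames(geneMap$gene, geneMap$snp)
  assoc <- assoc[!is.na(assoc$p), , drop = FALSE]
  gene <- geneMap[assoc$snp]
  if (anyNA(gene))
    stop("SNP(s) without gene assignment: ",
         paste(unique(assoc$snp[is.na(gene)])[1:5], collapse = ", "))
  key <- paste(assoc$variable, assoc$period, sep = "\r")
  out <- lapply(split(seq_len(nrow(assoc)), key), function(idx) {
    gi <- gene[idx]
    n <- tapply(rep(1L, length(idx)), gi, sum)
    a <- tapply(assoc$significant[idx], gi, sum)
    genes <- names(n)
    withHit <- a > 0
    if (!any(withHit)) return(NULL)
    P <- if (poolRule == "pooled") sum(a[withHit]) / sum(n[withHit])
         else mean((a / n)[withHit])
    qThr <- qbinom(quantile, n, P)      # smallest q with CDF >= quantile
    data.frame(gene = genes,
               variable = assoc$variable[idx[1]],
               period = assoc$period[idx[1]],
               n = as.integer(n), a = as.integer(a), P = P,
               qThreshold = as.integer(qThr),
               flagged = as.integer(a) > as.integer(qThr),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(gene = character(), variable = character(),
                      period = character(), n = integer(), a = integer(),
                      P = numeric(), qThreshold = integer(),
                      flagged = logical(), stringsAsFactors = FALSE)
    attr(out, "status") <- "inapplicable"
  }
  rownames(out) <- NULL
  out
}

#' Combine gene-level outliers with external SNP-level association calls
#'
#' A gene flagged by [geneOutlierTest()] for a (variable, period) is
#' retained as a top candidate only when at least \code{minSnps} distinct
#' SNPs in that gene are significant for the same variable (and, by
#' default, the same period) in the external calls; the two external
#' methods are pooled with OR semantics (a SNP counts if either method
#' fires).
#'
#' @param geneFlags data.frame from [geneOutlierTest()].
#' @param calls external-calls data.frame (see [readExternalCalls()]).
#' @param geneMap named character vector snp -> gene, or a data.frame with
#'   columns \code{snp} and \code{gene}.
#' @param minSnps minimum number of externally supported SNPs (default 2).
#' @param matchPeriod require the external call's period to match
#'   (default TRUE).
#' @return data.frame of retained candidates: \code{gene}, \code{variable},
#'   \code{period}, \code{geneLevel} (the gene's significant-SNP count a),
#'   \code{nBaypass}, \code{nBayescenv}, \code{nExternal}. When
#'   \code{calls} is empty the flagged genes are returned with
#'   \code{status = "unconfirmed"} attribute and no external counts.
#' @export
selectTopCandidates <- function(geneFlags, calls, geneMap, minSnps = 2L,
                                matchPeriod = TRUE) {
  flagged <- geneFlags[geneFlags$flagged, , drop = FALSE]
  if (is.null(calls) || nrow(calls) == 0) {
    attr(flagged, "status") <- "unconfirmed"
    return(flagged)
  }
  if (is.data.frame(geneMap))
    geneMap <- setNames(geneMap$gene, geneMap$snp)
  sig <- calls[calls$significant, , drop = FALSE]
  sig$gene <- geneMap[sig$snp]
  rows <- lapply(seq_len(nrow(flagged)), function(i) {
    fl <- flagged[i, ]
    hit <- sig$gene %in% fl$gene & sig$variable == fl$variable
    if (matchPeriod) hit <- hit & sig$period == fl$period
    sub <- sig[hit, , drop = FALSE]
    nBp <- length(unique(sub$snp[sub$method == "baypass"]))
    nBe <- length(unique(sub$snp[sub$method == "bayescenv"]))
    nAny <- length(unique(sub$snp))
    if (nAny < minSnps) return(NULL)
    data.frame(gene = fl$gene, variable = fl$variable, period = fl$period,
               geneLevel = fl$a, nBaypass = nBp, nBayescenv = nBe,
               nExternal = nAny, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(gene = character(), variable = character(),
                      period = character(), geneLevel = integer(),
                      nBaypass = integer(), nBayescenv = integer(),
                      nExternal = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
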