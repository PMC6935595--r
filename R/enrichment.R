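## Polygenic gene-set enrichment by the SUMSTAT score: a set's score is
## the plain sum of a per-gene statistic over its members, compared to a
## null distribution of same-size random gene sets. Overlap between sets
## is removed by iterative pruning, and the FDR is estimated empirically
## because pruned tests are neither independent nor unbiased.

#' @useDynLib adaptscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' SUMSTAT score of a gene set
#'
#' @param set character vector of member gene ids.
#' @param stats named numeric vector, gene id -> statistic value.
#' @param strict error (TRUE) or drop with a warning (FALSE, default) on
#'   member genes absent from \code{stats}.
#' @return the arithmetic sum of the members' statistic values.
#' @export
sumstat <- function(set, stats, strict = FALSE) {
  miss <- setdiff(set, names(stats))
  if (length(miss)) {
    if (strict) stop("gene(s) missing from statistics: ",
                     paste(miss, collapse = ", "))
    warning("dropping ", length(miss), " member gene(s) without statistic")
    set <- setdiff(set, miss)
  }
  sum(stats[set])
}

#' Test one gene set against a resampled SUMSTAT null
#'
#' Draws \code{nDraws} gene subsets of the same size as the set, uniformly
#' without replacement from the statistic universe, computes their SUMSTAT
#' scores, fits a normal distribution by their mean and standard deviation,
#' and reports \eqn{z = (SUMSTAT - \mu_0)/\sigma_0} with lower-tail
#' \eqn{p_{low} = \Phi(z)} and \eqn{p_{high} = 1 - p_{low}}. With
#' \code{pMode = "empirical"} the tail probabilities are the raw empirical
#' quantiles of the null draws instead (resolution limited to
#' \code{1/nDraws}). A constant universe (null standard deviation zero) is
#' degenerate and reported with both tail probabilities 0.5.
#'
#' @param set character vector of member gene ids.
#' @param stats named numeric vector over the sampling universe (all genes
#'   with a defined statistic); non-finite values are dropped upfront.
#' @param nDraws number of null sets (default 1e5).
#' @param seed optional integer; when given, the RNG is seeded so results
#'   are reproducible.
#' @param pMode \code{"normal"} (default) or \code{"empirical"}.
#' @return one-row data.frame: \code{size}, \code{sumstat},
#'   \code{nullMean}, \code{nullSd}, \code{z}, \code{pLow}, \code{pHigh},
#'   \code{degenerate}.
#' @export
sumstatTest <- function(set, stats, nDraws = 1e5, seed = NULL,
                        pMode = c("normal", "empirical")) {
  pMode <- match.arg(pMode)
  stats <- stats[is.finite(stats)]
  set <- intersect(set, names(stats))
  k <- length(set)
  if (k < 1) stop("empty set after intersection with the universe")
  if (k >= length(stats)) stop("universe must be larger than the set")
  if (!is.null(seed)) set.seed(seed)
  obs <- sum(stats[set])
  draws <- null_sumstats(unname(stats), k, as.integer(nDraws))
  mu <- mean(draws); sdv <- sd(draws)
  if (sdv == 0) {
    return(data.frame(size = k, sumstat = obs, nullMean = mu, nullSd = 0,
                      z = NA_real_, pLow = 0.5, pHigh = 0.5,
                      degenerate = TRUE))
  }
  z <- (obs - mu) / sdv
  if (pMode == "normal") {
    pLow <- pnorm(z); pHigh <- 1 - pLow
  } else {
    pLow <- mean(draws <= obs); pHigh <- mean(draws >= obs)
  }
  data.frame(size = k, sumstat = obs, nullMean = mu, nullSd = sdv, z = z,
             pLow = pLow, pHigh = pHigh, degenerate = FALSE)
}

#' Test a gene-set collection with iterative pruning of overlaps
#'
#' Repeatedly tests all surviving sets on the chosen tail, emits the
#' best-scoring (smallest tail-p) set with its current membership, removes
#' its genes from every remaining set, drops sets that fall below the
#' minimum size (recorded in the pruning trace), and re-tests until no set
#' remains. Ties on the minimal p are broken toward the larger |z|, then
#' the lexicographically smaller set id. The sampling universe is all
#' genes with a defined statistic and is kept fixed throughout.
#'
#' @param collection a [PathwayCollection-class] (or named list of gene-id
#'   vectors, minimum size 5).
#' @param stats named numeric vector, gene id -> statistic.
#' @param side tail to score: \code{"low"} or \code{"high"}.
#' @param nDraws null sets per test.
#' @param seed optional integer seed for the whole procedure.
#' @param pMode passed to [sumstatTest()].
#' @return list with \code{results} (data.frame in emission order: set id,
#'   \code{sizeBefore} the membership after intersection with the universe
#'   but before pruning, \code{sizeAfter} the tested membership, the
#'   [sumstatTest()] columns, \code{p} for the configured side and
#'   \code{order}) and \code{trace} (data.frame of pruning events).
#' @export
pruneAndTest <- function(collection, stats, side = c("low", "high"),
                         nDraws = 1e5, seed = NULL,
                         pMode = c("normal", "empirical")) {
  side <- match.arg(side); pMode <- match.arg(pMode)
  if (!is.null(seed)) set.seed(seed)
  minSize <- if (is(collection, "PathwayCollection"))
    minSetSize(collection) else 5L
  sets <- if (is(collection, "PathwayCollection")) collection@sets
          else collection
  stats <- stats[is.finite(stats)]
  sets <- lapply(sets, intersect, names(stats))
  sizeBefore <- lengths(sets)
  small <- names(sets)[lengths(sets) < minSize]
  sets <- sets[lengths(sets) >= minSize]

  results <- list()
  trace <- list()
  if (length(small))
    trace[[length(trace) + 1L]] <- data.frame(
      set = small, event = "below_min_size", iteration = 0L)
  it <- 0L
  while (length(sets)) {
    it <- it + 1L
    tested <- do.call(rbind, lapply(names(sets), function(id)
      cbind(set = id, sumstatTest(sets[[id]], stats, nDraws = nDraws,
                                  pMode = pMode))))
    tested$p <- if (side == "low") tested$pLow else tested$pHigh
    o <- order(tested$p, -abs(ifelse(is.na(tested$z), 0, tested$z)),
               tested$set)
    best <- tested[o[1L], , drop = FALSE]
    best$sizeBefore <- sizeBefore[[best$set]]
    best$sizeAfter <- best$size
    best$order <- it
    results[[it]] <- best
    trace[[length(trace) + 1L]] <- data.frame(
      set = best$set, event = "emitted", iteration = it)
    removed <- sets[[best$set]]
    sets <- sets[names(sets) != best$set]
    sets <- lapply(sets, setdiff, removed)
    dropped <- names(sets)[lengths(sets) < minSize]
    if (length(dropped)) {
      trace[[length(trace) + 1L]] <- data.frame(
        set = dropped, event = "pruned_out", iteration = it)
      sets <- sets[lengths(sets) >= minSize]
    }
  }
  results <- if (length(results)) do.call(rbind, results) else
    data.frame()
  rownames(results) <- NULL
  list(results = results,
       trace = do.call(rbind, c(trace, list(make.row.names = FALSE))))
}

#' Empirical FDR for pruned SUMSTAT results by whole-pipeline
#' randomization
#'
#' The pruning procedure keeps only the best set of each round, so its
#' p-values are biased low and a analytic FDR is not available. Instead the
#' gene-to-statistic assignment is permuted over the whole universe
#' \code{nIter} times, the complete [pruneAndTest()] pipeline is re-run on
#' each permutation with identical settings, and
#' \deqn{Q(p) = \frac{\mathrm{mean}_{iter}\,\#\{p' \le p\}}
#'                   {\max(1, \#\{p_{obs} \le p\})}}
#' is computed and monotonized to be non-decreasing in p (and capped at 1).
#'
#' @param observed the list returned by [pruneAndTest()] on the real data.
#' @param collection,stats,side,nDraws,pMode identical settings to the
#'   observed run.
#' @param nIter number of randomization iterations (default 300; fewer
#'   than 50 triggers a warning about unstable Q).
#' @param seed optional integer seed for the randomization stream.
#' @return the observed results data.frame with a \code{Q} column added.
#' @export
empiricalFdr <- function(observed, collection, stats,
                         side = c("low", "high"), nDraws = 1e5,
                         nIter = 300L, seed = NULL,
                         pMode = c("normal", "empirical")) {
  side <- match.arg(side); pMode <- match.arg(pMode)
  if (nIter < 50) warning("nIter < 50: empirical Q estimates are unstable")
  res <- observed$results
  if (is.null(res) || nrow(res) == 0) stop("observed results are empty")
  if (!is.null(seed)) set.seed(seed)
  stats <- stats[is.finite(stats)]
  nullP <- vector("list", nIter)
  for (b in seq_len(nIter)) {
    permStats <- setNames(sample(unname(stats)), names(stats))
    nullRun <- pruneAndTest(collection, permStats, side = side,
                            nDraws = nDraws, pMode = pMode)
    nullP[[b]] <- nullRun$results$p
  }
  allNull <- unlist(nullP)
  pObs <- res$p
  o <- order(pObs)
  qRaw <- vapply(pObs[o], function(p)
    (sum(allNull <= p) / nIter) / max(1, sum(pObs <= p)), 0)
  ## monotonize: Q(p_(i)) = min over j >= i of raw Q, then cap at 1
  qMono <- pmin(rev(cummin(rev(qRaw))), 1)
  res$Q <- NA_real_
  res$Q[o] <- qMono
  res
}
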