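## Seed-reproducible synthetic data with the statistical structure the
## analysis assumes: neutral coalescent gene alignments for calibrating
## the sequence statistics, population panels with planted climate clines
## for the association scans, and pathway universes with planted shifts
## for the enrichment test. All generators are pure functions of
## (config, seed).

#' Simulate one gene under the standard neutral coalescent
#'
#' Single-population Kingman coalescent with infinite-sites mutation:
#' while k lineages remain, an exponential waiting time with rate
#' \eqn{\binom{k}{2}} is drawn, every active lineage accumulates Poisson
#' mutations at rate \eqn{\theta/2} per unit coalescent time, and two
#' random lineages merge. Each mutation occupies a distinct position among
#' the L sites (ancestral state \code{"A"}, derived \code{"T"}).
#'
#' @param nCopies number of sampled allele copies (>= 2).
#' @param theta scaled mutation rate for the whole gene.
#' @param L total number of sites; must exceed the realized mutation
#'   count, otherwise an error asks for a larger L.
#' @param seed optional integer seed.
#' @return a [SiteAlignment-class] with L sites (monomorphic included).
#' @examples
#' al <- simulateCoalescentGene(10, theta = 5, L = 200, seed = 1)
#' siteSpectrumCounts(al)$S
#' @export
simulateCoalescentGene <- function(nCopies, theta, L, seed = NULL) {
  stopifnot(nCopies >= 2, theta > 0, L >= 1)
  if (!is.null(seed)) set.seed(seed)
  lineages <- as.list(seq_len(nCopies))
  carriers <- list()
  k <- nCopies
  while (k >= 2) {
    t <- rexp(1, rate = k * (k - 1) / 2)
    nMut <- rpois(k, theta / 2 * t)
    for (i in which(nMut > 0))
      carriers <- c(carriers, rep(lineages[i], nMut[i]))
    pair <- sample.int(k, 2)
    merged <- c(lineages[[pair[1]]], lineages[[pair[2]]])
    lineages <- c(lineages[-pair], list(merged))
    k <- k - 1L
  }
  M <- length(carriers)
  if (M > L)
    stop("realized mutation count (", M, ") exceeds L = ", L,
         "; increase L")
  al <- matrix("A", nCopies, L)
  if (M > 0) {
    pos <- sort(sample.int(L, M))
    for (j in seq_len(M)) al[carriers[[j]], pos[j]] <- "T"
  }
  SiteAlignment(al, geneId = "sim", positions = seq_len(L))
}

#' Default simulation configuration for a population panel
#'
#' The defaults emulate the sampling design the pipeline targets: 12
#' populations of 10 diploids, ~1,100 genes carrying several SNPs each,
#' eight bioclimatic variables in three periods (present, last glacial
#' maximum, last interglacial) with strong across-period correlation, a
#' small fraction of SNPs with clinal allele frequencies tied to one
#' climate column, and an external association-call table with fixed
#' sensitivity and false-positive rate.
#'
#' @param ... overrides for any configuration entry.
#' @return named list of simulation parameters.
#' @export
simulationConfig <- function(...) {
  cfg <- list(
    nPopulations = 12L,
    diploidsPerPop = 10L,
    nGenes = 1100L,
    snpsPerGeneMean = 22,        # Poisson mean, floored at 1
    fst = 0.1,                   # hierarchical beta differentiation
    missingRate = 0.02,
    variables = c("tmean", "tseas", "tmaxwarm", "tmincold",
                  "pann", "pwet", "pdry", "pseas"),
    periods = c("PRE", "LGM", "LIG"),
    climateMeans = c(tmean = 8, tseas = 6, tmaxwarm = 24, tmincold = -3,
                     pann = 900, pwet = 120, pdry = 40, pseas = 35),
    climateSds = c(tmean = 4, tseas = 1.5, tmaxwarm = 4, tmincold = 4,
                   pann = 300, pwet = 40, pdry = 25, pseas = 12),
    periodShift = c(PRE = 0, LGM = -1.5, LIG = 0.3),  # in SD units
    crossPeriodCor = 0.8,
    clinalFraction = 0.02,
    beta = 2,                    # logit-scale climate effect
    clinalNoiseSd = 0.5,         # logit-scale residual noise
    coverageMean = 80, coverageSd = 30,
    nSets = 60L, setSizeRange = c(5L, 15L),
    externalSensitivity = 0.8,
    externalFpr = 0.01)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Recode alternate-allele copy counts to minor-allele copy counts
#' @noRd
.recodeMinor <- function(altCopies, ref, alt) {
  nObs <- rowSums(!is.na(altCopies))
  altTot <- rowSums(altCopies, na.rm = TRUE)
  refTot <- 2L * nObs - altTot
  minorIsAlt <- altTot < refTot | (altTot == refTot & alt < ref)
  geno <- altCopies
  geno[!minorIsAlt, ] <- 2L - altCopies[!minorIsAlt, , drop = FALSE]
  storage.mode(geno) <- "integer"
  list(geno = geno, minorAllele = ifelse(minorIsAlt, alt, ref))
}

#' Simulate a population panel with planted climate clines
#'
#' Climate values are drawn per population, variable and period with the
#' configured across-period correlation. Neutral SNPs receive population
#' allele frequencies from a Balding-Nichols-style beta draw around a
#' global frequency with differentiation parameter \code{fst}; clinal SNPs
#' follow \eqn{logit^{-1}(a + \beta z + \epsilon)} of the standardized
#' target climate column, which yields monotone frequency--climate
#' relations detectable by rank correlation. Genotypes are sampled
#' binomially (two copies per diploid) with independent missingness, and
#' the external-calls table marks planted SNPs significant with the
#' configured sensitivity and null SNPs at the configured false-positive
#' rate.
#'
#' @param config list from [simulationConfig()].
#' @param seed optional integer seed.
#' @return list with \code{dataset} (a [GeaDataset-class]) and
#'   \code{truth} (planted clinal SNPs with their gene, climate column and
#'   effect size).
#' @export
simulatePopulationPanel <- function(config = simulationConfig(),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  nPop <- cfg$nPopulations
  pops <- sprintf("pop%02d", seq_len(nPop))
  samples <- paste0(rep(pops, each = cfg$diploidsPerPop), "_",
                    sprintf("i%02d", seq_len(cfg$diploidsPerPop)))
  popOf <- setNames(rep(pops, each = cfg$diploidsPerPop), samples)

  ## climate: latent per (variable, population), periods correlated
  cols <- as.vector(outer(cfg$variables, cfg$periods, paste, sep = "_"))
  climate <- matrix(NA_real_, nPop, length(cols),
                    dimnames = list(pops, cols))
  rho <- cfg$crossPeriodCor
  for (v in cfg$variables) {
    z <- rnorm(nPop)
    for (per in cfg$periods) {
      e <- rnorm(nPop)
      zp <- rho * z + sqrt(1 - rho^2) * e
      climate[, paste(v, per, sep = "_")] <-
        cfg$climateMeans[[v]] + cfg$climateSds[[v]] *
          (zp + cfg$periodShift[[per]])
    }
  }

  ## genes and SNP counts
  nSnpPerGene <- pmax(1L, rpois(cfg$nGenes, cfg$snpsPerGeneMean))
  genes <- sprintf("gene%05d", seq_len(cfg$nGenes))
  geneOfSnp <- rep(genes, nSnpPerGene)
  nSnp <- length(geneOfSnp)
  snpIds <- sprintf("snp%06d", seq_len(nSnp))

  ## plant clines gene-coherently: a clinal gene carries several SNPs
  ## responding to one shared climate column (mimicking intra-gene LD
  ## around a causal variant), until the SNP budget is spent
  target <- round(cfg$clinalFraction * nSnp)
  clinalIdx <- integer(0)
  clinalCol <- character(0)
  if (target > 0) {
    for (gi in sample(seq_len(cfg$nGenes))) {
      if (length(clinalIdx) >= target) break
      snpsIn <- which(geneOfSnp == genes[gi])
      k <- min(length(snpsIn), max(2L, ceiling(length(snpsIn) / 2)),
               max(2L, target - length(clinalIdx)))
      pick <- sample(snpsIn, k)
      clinalIdx <- c(clinalIdx, pick)
      clinalCol <- c(clinalCol, rep(sample(cols, 1), k))
    }
    o <- order(clinalIdx)
    clinalIdx <- clinalIdx[o]
    clinalCol <- clinalCol[o]
  }
  nClinal <- length(clinalIdx)

  ## population frequencies of the alternate allele
  pGlobal <- runif(nSnp, 0.05, 0.5)
  popFreq <- matrix(NA_real_, nSnp, nPop)
  Fst <- cfg$fst
  shape1 <- pGlobal * (1 - Fst) / Fst
  shape2 <- (1 - pGlobal) * (1 - Fst) / Fst
  for (j in seq_len(nPop))
    popFreq[, j] <- rbeta(nSnp, shape1, shape2)
  if (nClinal > 0) {
    for (t in seq_len(nClinal)) {
      i <- clinalIdx[t]
      zClim <- scale(climate[, clinalCol[t]])[, 1]
      popFreq[i, ] <- plogis(qlogis(pGlobal[i]) + cfg$beta * zClim +
                             rnorm(nPop, 0, cfg$clinalNoiseSd))
    }
  }

  ## genotypes: binomial(2, freq) with missingness
  altCopies <- matrix(NA_integer_, nSnp, length(samples),
                      dimnames = list(snpIds, samples))
  for (j in seq_along(samples)) {
    pj <- popFreq[, match(popOf[j], pops)]
    altCopies[, j] <- rbinom(nSnp, 2L, pj)
  }
  if (cfg$missingRate > 0) {
    miss <- matrix(runif(length(altCopies)) < cfg$missingRate,
                   nrow = nSnp)
    altCopies[miss] <- NA_integer_
  }

  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, nSnp, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1), "")
  rec <- .recodeMinor(altCopies, ref, alt)

  coverage <- pmax(5, rnorm(nSnp, cfg$coverageMean, cfg$coverageSd))
  hasHet <- rowSums(rec$geno == 1L, na.rm = TRUE) > 0
  ab <- ifelse(hasHet, pmin(0.95, pmax(0.05, rnorm(nSnp, 0.5, 0.04))),
               NA_real_)
  meta <- data.frame(
    snp = snpIds, chrom = geneOfSnp,
    pos = unlist(lapply(nSnpPerGene, function(k) sort(sample.int(5000, k)))),
    ref = ref, alt = alt, minorAllele = rec$minorAllele,
    nAlleles = 2L, coverage = round(coverage, 1), alleleBalance = round(ab, 3),
    missingFrac = rowMeans(is.na(rec$geno)),
    gene = geneOfSnp, siteClass = sample(c("syn", "nonsyn", "other"),
                                         nSnp, TRUE, c(0.25, 0.5, 0.25)),
    stringsAsFactors = FALSE)

  ## pathways over a subset of genes
  sizes <- sample(seq(cfg$setSizeRange[1], cfg$setSizeRange[2]),
                  cfg$nSets, replace = TRUE)
  sets <- setNames(lapply(sizes, function(k) sample(genes, k)),
                   sprintf("path%03d", seq_len(cfg$nSets)))

  ## external calls: planted hits by sensitivity, null noise by FPR
  extRows <- list()
  if (nClinal > 0) {
    fires <- runif(nClinal * 2)  # per method
    for (t in seq_len(nClinal)) {
      vp <- strsplit(clinalCol[t], "_", fixed = TRUE)[[1]]
      for (mi in 1:2) {
        method <- c("baypass", "bayescenv")[mi]
        hit <- fires[2 * (t - 1) + mi] < cfg$externalSensitivity
        score <- if (method == "baypass") {
          if (hit) runif(1, 31, 80) else runif(1, 0, 20)
        } else if (hit) runif(1, 0, 0.049) else runif(1, 0.06, 1)
        extRows[[length(extRows) + 1L]] <- data.frame(
          snp = snpIds[clinalIdx[t]], variable = vp[1], period = vp[2],
          method = method, score = score, significant = hit,
          stringsAsFactors = FALSE)
      }
    }
  }
  nullIdx <- setdiff(seq_len(nSnp), clinalIdx)
  nFp <- rbinom(1, 2L * length(nullIdx), cfg$externalFpr)
  if (nFp > 0) {
    pickSnp <- sample(nullIdx, nFp, replace = TRUE)
    pickCol <- sample(cols, nFp, replace = TRUE)
    pickMethod <- sample(c("baypass", "bayescenv"), nFp, replace = TRUE)
    for (t in seq_len(nFp)) {
      vp <- strsplit(pickCol[t], "_", fixed = TRUE)[[1]]
      score <- if (pickMethod[t] == "baypass") runif(1, 31, 50)
               else runif(1, 0, 0.049)
      extRows[[length(extRows) + 1L]] <- data.frame(
        snp = snpIds[pickSnp[t]], variable = vp[1], period = vp[2],
        method = pickMethod[t], score = score, significant = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  ext <- if (length(extRows)) do.call(rbind, extRows) else data.frame()

  ds <- GeaDataset(rec$geno, meta, popOf, climate = climate,
                   pathways = sets, externalCalls = ext)
  truth <- list(
    clinalSnps = if (nClinal > 0) data.frame(
      snp = snpIds[clinalIdx], gene = geneOfSnp[clinalIdx],
      variable = sub("_[^_]+$", "", clinalCol),
      period = sub("^.*_", "", clinalCol),
      beta = cfg$beta, stringsAsFactors = FALSE)
    else data.frame(),
    config = cfg)
  list(dataset = ds, truth = truth)
}

#' Simulate a gene-statistic universe with a planted shifted pathway
#'
#' Gene statistics are standard normal; the members of one designated set
#' are shifted by \code{delta}. Optionally a nested pair of sets is
#' engineered (one set a strict subset of another) to exercise the pruning
#' logic.
#'
#' @param nGenes universe size.
#' @param nSets number of gene sets.
#' @param setSize members per set.
#' @param delta per-gene shift applied to the planted set (first set); 0
#'   plants nothing.
#' @param seed optional integer seed.
#' @param nested when TRUE, the last set is replaced by a strict subset of
#'   the first one.
#' @return list with \code{stats} (named numeric), \code{collection} (a
#'   [PathwayCollection-class]) and \code{truth} (planted set id and
#'   delta).
#' @export
simulatePathwayUniverse <- function(nGenes = 300L, nSets = 8L,
                                    setSize = 10L, delta = 1,
                                    seed = NULL, nested = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("g%04d", seq_len(nGenes))
  stats <- setNames(rnorm(nGenes), genes)
  sets <- setNames(lapply(seq_len(nSets), function(i)
    sample(genes, setSize)), sprintf("set%02d", seq_len(nSets)))
  planted <- names(sets)[1]
  if (delta != 0)
    stats[sets[[planted]]] <- stats[sets[[planted]]] + delta
  if (nested && nSets >= 2) {
    child <- sample(sets[[1]], max(2L, floor(setSize / 2)))
    sets[[nSets]] <- child
  }
  list(stats = stats, collection = PathwayCollection(sets),
       truth = list(planted = planted, delta = delta,
                    nested = if (nested) names(sets)[nSets] else NA))
}

#' Write a simulated panel as a plain-text fixture bundle
#'
#' Emits the VCF, popmap TSV, gene-map TSV, climate CSV, GMT gene sets,
#' external-calls TSV and a truth JSON into \code{outDir}, such that
#' [loadDataset()] on the bundle round-trips the genotype matrix exactly.
#'
#' @param panel list returned by [simulatePopulationPanel()].
#' @param outDir output directory (created if needed).
#' @return named character vector of the file paths written (also usable
#'   as the \code{config} of [loadDataset()] after renaming).
#' @export
writeFixtureBundle <- function(panel, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ds <- panel$dataset
  paths <- c(vcf = file.path(outDir, "genotypes.vcf"),
             popmap = file.path(outDir, "popmap.tsv"),
             geneMap = file.path(outDir, "gene_map.tsv"),
             climate = file.path(outDir, "climate.csv"),
             geneSets = file.path(outDir, "gene_sets.gmt"),
             externalCalls = file.path(outDir, "external_calls.tsv"),
             truth = file.path(outDir, "truth.json"))
  writeVcf(ds, paths[["vcf"]])
  pm <- popmap(ds)
  write.table(data.frame(sample = names(pm), population = unname(pm)),
              paths[["popmap"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  m <- snpMeta(ds)
  write.table(data.frame(snp_id = m$snp, gene_id = m$gene,
                         site_class = m$siteClass),
              paths[["geneMap"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  cl <- climateMatrix(ds)
  long <- expand.grid(population = rownames(cl), col = colnames(cl),
                      stringsAsFactors = FALSE)
  long$variable <- sub("_[^_]+$", "", long$col)
  long$period <- sub("^.*_", "", long$col)
  long$value <- cl[cbind(long$population, long$col)]
  write.table(long[, c("population", "variable", "period", "value")],
              paths[["climate"]], sep = ",", quote = FALSE,
              row.names = FALSE)
  writeGmt(geneSets(ds), paths[["geneSets"]])
  ext <- externalCalls(ds)
  if (nrow(ext)) {
    write.table(data.frame(snp_id = ext$snp, variable = ext$variable,
                           period = ext$period, method = ext$method,
                           score = ext$score, significant = ext$significant),
                paths[["externalCalls"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    writeLines("snp_id\tvariable\tperiod\tmethod\tscore\tsignificant",
               paths[["externalCalls"]])
  }
  jsonlite::write_json(panel$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}
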