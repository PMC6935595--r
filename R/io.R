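## Readers for the standard input formats and assembly of the unified
## GeaDataset. VCF parsing is delegated to vcfR; genotypes are re-expressed
## as copy counts of the globally defined minor allele (ties at frequency
## 0.5 broken toward the lexicographically smaller allele string).

#' Read a popmap TSV (sample, population)
#' @param path TSV file with a header line \code{sample<TAB>population}.
#' @return named character vector, sample -> population.
#' @export
readPopmap <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  setNames(as.character(d$population), as.character(d$sample))
}

#' Read a long-format climate CSV into a population x column matrix
#'
#' Expects columns \code{population}, \code{variable}, \code{period},
#' \code{value}; the result has one row per population and one column per
#' \code{"<variable>_<period>"} combination.
#' @param path CSV file path.
#' @return numeric matrix.
#' @export
readClimate <- function(path) {
  d <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  cols <- unique(paste(d$variable, d$period, sep = "_"))
  pops <- unique(d$population)
  m <- matrix(NA_real_, length(pops), length(cols),
              dimnames = list(pops, cols))
  m[cbind(match(d$population, pops),
          match(paste(d$variable, d$period, sep = "_"), cols))] <- d$value
  m
}

#' Read gene sets in GMT format
#'
#' Tab-separated lines: set id, description, then member gene ids.
#' @param path GMT file path.
#' @param minSize minimum testable set size stored with the collection.
#' @return a [PathwayCollection-class].
#' @export
readGmt <- function(path, minSize = 5L) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1L)
  desc <- setNames(vapply(parts, `[`, "", 2L), ids)
  sets <- setNames(lapply(parts, function(p) unique(p[-(1:2)])), ids)
  PathwayCollection(sets, desc, minSize = minSize)
}

#' Write gene sets in GMT format
#' @param x a [PathwayCollection-class] or named list of gene-id vectors.
#' @param path output file path.
#' @export
writeGmt <- function(x, path) {
  sets <- if (is(x, "PathwayCollection")) x@sets else x
  desc <- if (is(x, "PathwayCollection")) x@description else
    setNames(rep(NA_character_, length(sets)), names(sets))
  lines <- vapply(names(sets), function(id) {
    d <- desc[[id]]
    paste(c(id, ifelse(is.na(d), "na", d), sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
}

#' Read a SNP-to-gene map TSV
#'
#' Columns \code{snp_id}, \code{gene_id} and optionally \code{site_class}
#' (one of \code{syn}, \code{nonsyn}, \code{other}).
#' @param path TSV file path.
#' @return data.frame with columns \code{snp}, \code{gene}, \code{siteClass}.
#' @export
readGeneMap <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  out <- data.frame(snp = as.character(d$snp_id),
                    gene = as.character(d$gene_id),
                    stringsAsFactors = FALSE)
  out$siteClass <- if ("site_class" %in% names(d))
    as.character(d$site_class) else "other"
  out
}

#' Read external SNP-level association calls
#'
#' TSV with columns \code{snp_id}, \code{variable}, \code{period},
#' \code{method} (\code{bayescenv} or \code{baypass}), \code{score} and
#' optionally \code{significant}. When \code{significant} is absent it is
#' derived from the conventional thresholds: Q-value < 0.05 for bayescenv
#' scores, Bayes factor > 30 for baypass scores. When both are present an
#' inconsistency raises a warning.
#' @param path TSV file path.
#' @return data.frame with columns \code{snp}, \code{variable},
#'   \code{period}, \code{method}, \code{score}, \code{significant}.
#' @export
readExternalCalls <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  out <- data.frame(snp = as.character(d$snp_id),
                    variable = as.character(d$variable),
                    period = as.character(d$period),
                    method = as.character(d$method),
                    score = as.numeric(d$score),
                    stringsAsFactors = FALSE)
  derived <- ifelse(out$method == "bayescenv", out$score < 0.05,
             ifelse(out$method == "baypass", out$score > 30, NA))
  if ("significant" %in% names(d)) {
    out$significant <- as.logical(d$significant)
    bad <- !is.na(out$score) & !is.na(derived) & out$significant != derived
    if (any(bad))
      warning(sum(bad), " external call(s) have a significance flag ",
              "inconsistent with the method's score threshold")
  } else {
    out$significant <- derived
  }
  out
}

#' Extract minor-allele copy counts and per-SNP metadata from a vcfR object
#' @noRd
.vcfToGenotypes <- function(vcf) {
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  rownames(gt) <- ids

  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  nAlt <- ifelse(is.na(alt) | alt == ".", 0L,
                 lengths(strsplit(alt, ",", fixed = TRUE)))

  ## allele-copy counts per allele index (0 = ref) from GT strings
  gtClean <- gsub("|", "/", gt, fixed = TRUE)
  a1 <- sub("/.*", "", gtClean)
  a2 <- sub(".*/", "", gtClean)
  a1[a1 == "."] <- NA; a2[a2 == "."] <- NA
  a1 <- matrix(suppressWarnings(as.integer(a1)), nrow = nrow(gt))
  a2 <- matrix(suppressWarnings(as.integer(a2)), nrow = nrow(gt))

  maxAll <- max(nAlt, 1L)
  counts <- matrix(0L, nrow(gt), maxAll + 1L)
  for (k in 0:maxAll) {
    counts[, k + 1L] <- rowSums(a1 == k, na.rm = TRUE) +
      rowSums(a2 == k, na.rm = TRUE)
  }

  ## choose the minor allele per SNP over the full sample
  minorIdx <- integer(nrow(gt))
  minorStr <- character(nrow(gt))
  altList <- strsplit(ifelse(is.na(alt), "", alt), ",", fixed = TRUE)
  for (i in seq_len(nrow(gt))) {
    strs <- c(ref[i], altList[[i]])
    cts <- counts[i, seq_along(strs)]
    present <- which(cts > 0)
    if (length(present) == 0L) present <- 1L
    o <- present[order(cts[present], strs[present])]
    minorIdx[i] <- o[1L] - 1L
    minorStr[i] <- strs[o[1L]]
  }

  geno <- (a1 == minorIdx) + (a2 == minorIdx)
  storage.mode(geno) <- "integer"
  dimnames(geno) <- dimnames(gt)

  ## mean coverage across samples (FORMAT/DP)
  coverage <- rep(NA_real_, nrow(gt))
  dp <- tryCatch(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE),
                 error = function(e) NULL)
  if (!is.null(dp) && !all(is.na(dp)))
    coverage <- rowMeans(dp, na.rm = TRUE)

  ## allele balance of heterozygous calls (FORMAT/AD, alt fraction)
  ab <- rep(NA_real_, nrow(gt))
  ad <- tryCatch(vcfR::extract.gt(vcf, element = "AD"),
                 error = function(e) NULL)
  if (!is.null(ad) && !all(is.na(ad))) {
    het <- !is.na(a1) & !is.na(a2) & a1 != a2
    adRef <- suppressWarnings(as.numeric(sub(",.*", "", ad)))
    adAlt <- suppressWarnings(as.numeric(
      vapply(strsplit(ad, ",", fixed = TRUE),
             function(p) if (length(p) >= 2) p[2] else NA_character_, "")))
    frac <- matrix(adAlt / (adRef + adAlt), nrow = nrow(gt))
    frac[!het] <- NA
    ab <- rowMeans(frac, na.rm = TRUE)
    ab[is.nan(ab)] <- NA_real_
  }

  nCopies <- rowSums(!is.na(a1)) + rowSums(!is.na(a2))
  meta <- data.frame(
    snp = ids,
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = ref,
    alt = alt,
    minorAllele = minorStr,
    nAlleles = rowSums(counts > 0),
    coverage = coverage,
    alleleBalance = ab,
    missingFrac = 1 - nCopies / (2 * ncol(gt)),
    stringsAsFactors = FALSE)
  list(genotypes = geno, meta = meta)
}

#' Load and assemble a unified dataset from standard files
#'
#' Reads genotypes (VCF), the popmap, and optionally the climate table, the
#' SNP-to-gene map, the gene sets (GMT) and external association calls, and
#' assembles a validated [GeaDataset-class]. Genotypes are re-expressed as
#' copy counts of the minor allele defined over the full sample; a frequency
#' tie at 0.5 is broken toward the lexicographically smaller allele string.
#'
#' @param config named list of file paths with elements \code{vcf} and
#'   \code{popmap} (required) and optionally \code{climate}, \code{geneMap},
#'   \code{geneSets}, \code{externalCalls}; plus option
#'   \code{onMissingGene}, one of \code{"drop"} (default; SNPs without a gene
#'   assignment are dropped with a warning when a gene map is supplied) or
#'   \code{"error"}.
#' @return a [GeaDataset-class].
#' @examples
#' \dontrun{
#' ds <- loadDataset(list(vcf = "calls.vcf", popmap = "popmap.tsv",
#'                        climate = "climate.csv", geneMap = "genes.tsv"))
#' }
#' @export
loadDataset <- function(config) {
  stopifnot(is.list(config), !is.null(config$vcf), !is.null(config$popmap))
  onMissingGene <- match.arg(config$onMissingGene %||% "drop",
                             c("drop", "error"))
  vcf <- vcfR::read.vcfR(config$vcf, verbose = FALSE)
  gg <- .vcfToGenotypes(vcf)
  pm <- readPopmap(config$popmap)
  absent <- setdiff(colnames(gg$genotypes), names(pm))
  if (length(absent))
    stop("sample(s) absent from popmap: ", paste(absent, collapse = ", "))

  meta <- gg$meta
  geno <- gg$genotypes
  if (!is.null(config$geneMap)) {
    gm <- readGeneMap(config$geneMap)
    idx <- match(meta$snp, gm$snp)
    meta$gene <- gm$gene[idx]
    meta$siteClass <- gm$siteClass[idx]
    if (anyNA(meta$gene)) {
      n <- sum(is.na(meta$gene))
      if (onMissingGene == "error")
        stop(n, " SNP(s) without gene assignment")
      warning("dropping ", n, " SNP(s) without gene assignment")
      keep <- !is.na(meta$gene)
      meta <- meta[keep, , drop = FALSE]
      geno <- geno[keep, , drop = FALSE]
    }
  } else {
    meta$gene <- meta$chrom
    meta$siteClass <- "other"
  }

  climate <- if (!is.null(config$climate)) readClimate(config$climate)
             else matrix(numeric(0), 0, 0)
  pathways <- if (!is.null(config$geneSets)) readGmt(config$geneSets)@sets
              else list()
  ext <- if (!is.null(config$externalCalls))
    readExternalCalls(config$externalCalls) else data.frame()

  GeaDataset(geno, meta, pm, climate = climate, pathways = pathways,
             externalCalls = ext)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a GeaDataset genotype matrix as a plain-text VCF
#'
#' Emits a minimal VCF 4.2 with GT, DP and AD FORMAT fields reconstructed
#' from the stored per-SNP coverage and heterozygote allele balance, so that
#' [loadDataset()] round-trips the genotype matrix exactly.
#' @param ds a [GeaDataset-class].
#' @param path output path (uncompressed \code{.vcf}).
#' @export
writeVcf <- function(ds, path) {
  g <- genotypes(ds)
  m <- snpMeta(ds)
  samples <- colnames(g)
  hdr <- c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  rows <- vapply(seq_len(nrow(g)), function(i) {
    minorIsAlt <- identical(m$minorAllele[i], m$alt[i])
    dp <- if (is.na(m$coverage[i])) 30L else as.integer(round(m$coverage[i]))
    ab <- if (is.na(m$alleleBalance[i])) 0.5 else m$alleleBalance[i]
    cells <- vapply(g[i, ], function(x) {
      if (is.na(x)) return("./.:.:.")
      altCopies <- if (minorIsAlt) x else 2L - x
      gtStr <- c("0/0", "0/1", "1/1")[altCopies + 1L]
      adAlt <- switch(as.character(altCopies), "0" = 0L,
                      "1" = as.integer(round(dp * ab)), "2" = dp)
      paste0(gtStr, ":", dp, ":", dp - adAlt, ",", adAlt)
    }, "")
    paste(c(m$chrom[i], m$pos[i], m$snp[i], m$ref[i], m$alt[i], ".", "PASS",
            ".", "GT:DP:AD", cells), collapse = "\t")
  }, "")
  writeLines(c(hdr, rows), path)
}

#' Read a per-gene FASTA alignment into a SiteAlignment
#'
#' Sequences must be pre-aligned (equal length). Characters outside
#' A/C/G/T (gaps, N and other ambiguity codes) become missing copies.
#' Unphased diploid consensus sequences should be supplied as two rows per
#' individual when heterozygous phase is immaterial.
#'
#' @param path FASTA file.
#' @param geneId gene identifier (defaults to the file name).
#' @param weights optional L x 3 site-class weight matrix (see
#'   [SiteAlignment()]).
#' @return a [SiteAlignment-class].
#' @export
readFastaAlignment <- function(path, geneId = NULL, weights = NULL) {
  seqs <- ape::read.FASTA(path)
  chars <- lapply(as.character(seqs), toupper)
  L <- unique(lengths(chars))
  if (length(L) != 1L)
    stop("sequences differ in length; not an alignment")
  m <- do.call(rbind, chars)
  m[!m %in% c("A", "C", "G", "T")] <- NA_character_
  SiteAlignment(m, geneId = geneId %||% basename(path), weights = weights)
}
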