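#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor pbinom pnorm pt qbinom rbeta rbinom rexp rnorm
#'   rpois runif sd setNames var plogis qlogis
#' @importFrom utils read.table write.table
NULL

## Missing allele-copy sentinel used throughout: NA (R native). Genotypes are
## integer minor-allele copy counts in {0, 1, 2, NA}.

#' Per-gene allele matrix with site-class weights
#'
#' A \code{SiteAlignment} stores the 2N allele copies observed at each site of
#' one gene, including monomorphic sites, together with fractional site-class
#' weights used to partition diversity into synonymous and nonsynonymous
#' components. Unphased diploids contribute two allele copies per site; a
#' missing copy is \code{NA}. The class weights at each site must sum to 1.
#'
#' @slot geneId single gene identifier.
#' @slot alleles character matrix, allele copies (rows, 2N) x sites (columns,
#'   L); entries are allele strings (e.g. bases) or \code{NA} for missing.
#' @slot positions integer vector of 1-based site positions (length L).
#' @slot weights numeric L x 3 matrix with columns \code{syn}, \code{nonsyn},
#'   \code{other}; rows sum to 1.
#'
#' @seealso [nucleotideDiversity()], [siteSpectrumCounts()],
#'   [simulateCoalescentGene()]
#' @export
setClass("SiteAlignment",
  representation(
    geneId = "character",
    alleles = "matrix",
    positions = "integer",
    weights = "matrix"
  )
)

setValidity("SiteAlignment", function(object) {
  msg <- NULL
  L <- ncol(object@alleles)
  if (length(object@geneId) != 1L)
    msg <- c(msg, "geneId must be a single string")
  if (length(object@positions) != L)
    msg <- c(msg, "positions length must equal number of sites")
  if (!identical(dim(object@weights), c(L, 3L)))
    msg <- c(msg, "weights must be an L x 3 matrix")
  else {
    if (!identical(colnames(object@weights), c("syn", "nonsyn", "other")))
      msg <- c(msg, "weights columns must be syn, nonsyn, other")
    if (L > 0L && any(abs(rowSums(object@weights) - 1) > 1e-8))
      msg <- c(msg, "site-class weights must sum to 1 at every site")
    if (L > 0L && any(object@weights < -1e-12))
      msg <- c(msg, "site-class weights must be non-negative")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a SiteAlignment
#'
#' @param alleles character matrix of allele copies x sites (\code{NA} =
#'   missing copy).
#' @param geneId gene identifier.
#' @param positions optional 1-based positions; defaults to \code{1:L}.
#' @param weights optional L x 3 site-class weight matrix (columns
#'   \code{syn}, \code{nonsyn}, \code{other}); defaults to all weight on
#'   \code{other}, i.e. no coding annotation.
#' @return a [SiteAlignment-class] object.
#' @examples
#' al <- SiteAlignment(rbind(c("A", "A"), c("A", "T"), c("A", "T"), c("A", "T")))
#' nucleotideDiversity(al)
#' @export
SiteAlignment <- function(alleles, geneId = "gene", positions = NULL,
                          weights = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "character"
  L <- ncol(alleles)
  if (is.null(positions)) positions <- seq_len(L)
  if (is.null(weights)) {
    weights <- cbind(syn = numeric(L), nonsyn = numeric(L),
                     other = rep(1, L))
  }
  weights <- as.matrix(weights)
  colnames(weights) <- c("syn", "nonsyn", "other")
  new("SiteAlignment", geneId = as.character(geneId), alleles = alleles,
      positions = as.integer(positions), weights = weights)
}

#' @describeIn SiteAlignment-class number of sites (columns), including
#'   monomorphic ones.
#' @param x,object a \code{SiteAlignment}.
#' @export
setMethod("length", "SiteAlignment", function(x) ncol(x@alleles))

setMethod("show", "SiteAlignment", function(object) {
  cat("SiteAlignment '", object@geneId, "': ",
      nrow(object@alleles), " allele copies x ",
      ncol(object@alleles), " sites\n", sep = "")
})

#' Allele matrix of a SiteAlignment
#' @param x a [SiteAlignment-class].
#' @return character matrix, copies x sites.
#' @export
alleleMatrix <- function(x) x@alleles

#' Site-class weight matrix of a SiteAlignment
#' @param x a [SiteAlignment-class].
#' @return numeric L x 3 matrix (syn, nonsyn, other).
#' @export
siteWeights <- function(x) x@weights

#' Gene-set collection with a minimum-size rule
#'
#' Holds pathway (gene-set) membership as a named list of gene-identifier
#' vectors, with free-text descriptions and the minimum number of member
#' genes a set must retain (after intersection with the measured gene
#' universe) to be tested.
#'
#' @slot sets named list of character vectors of gene ids.
#' @slot description named character vector of set descriptions.
#' @slot minSize single integer, minimum set size (default 5).
#' @export
setClass("PathwayCollection",
  representation(
    sets = "list",
    description = "character",
    minSize = "integer"
  )
)

setValidity("PathwayCollection", function(object) {
  msg <- NULL
  if (is.null(names(object@sets)) && length(object@sets) > 0L)
    msg <- c(msg, "sets must be named")
  if (anyDuplicated(names(object@sets)))
    msg <- c(msg, "set ids must be unique")
  if (length(object@minSize) != 1L || object@minSize < 1L)
    msg <- c(msg, "minSize must be a single positive integer")
  if (is.null(msg)) TRUE else msg
})

#' Construct a PathwayCollection
#'
#' @param sets named list of character vectors (set id -> member gene ids).
#' @param description optional named character vector of descriptions.
#' @param minSize minimum member count for a set to be testable (default 5,
#'   the usual gene-set enrichment floor).
#' @return a [PathwayCollection-class].
#' @export
PathwayCollection <- function(sets, description = NULL, minSize = 5L) {
  if (is.null(description))
    description <- setNames(rep(NA_character_, length(sets)), names(sets))
  new("PathwayCollection", sets = lapply(sets, as.character),
      description = description, minSize = as.integer(minSize))
}

#' @describeIn PathwayCollection-class number of gene sets.
#' @param x,object a \code{PathwayCollection}.
#' @export
setMethod("length", "PathwayCollection", function(x) length(x@sets))

setMethod("show", "PathwayCollection", function(object) {
  cat("PathwayCollection: ", length(object@sets), " sets, minSize = ",
      object@minSize, "\n", sep = "")
  if (length(object@sets)) {
    sz <- lengths(object@sets)
    cat("  set sizes: ", min(sz), "-", max(sz), " genes\n", sep = "")
  }
})

#' Gene-set membership list
#' @param x a [PathwayCollection-class].
#' @return named list of character vectors.
#' @export
geneSets <- function(x) {
  if (is(x, "PathwayCollection")) x@sets
  else if (is(x, "GeaDataset")) x@pathways
  else stop("no gene sets in object of class ", class(x))
}

#' Minimum testable set size
#' @param x a [PathwayCollection-class].
#' @export
minSetSize <- function(x) x@minSize

#' Unified genotype--environment dataset
#'
#' \code{GeaDataset} extends \link[SummarizedExperiment]{SummarizedExperiment}.
#' The single assay \code{"geno"} is an integer SNP x sample matrix of
#' minor-allele copy counts (0/1/2, \code{NA} missing); \code{rowData} carries
#' per-SNP metadata (\code{snp}, \code{gene}, \code{pos}, \code{ref},
#' \code{alt}, \code{coverage}, \code{alleleBalance}, \code{siteClass});
#' \code{colData$population} is the population map. Additional slots hold the
#' population x (variable, period) climate matrix, the pathway collection and
#' the external SNP-level association calls consumed by the candidate-gene
#' combination rule.
#'
#' @slot climate numeric matrix, populations (rows) x climate columns named
#'   \code{"<variable>_<period>"}.
#' @slot pathways named list of gene-id vectors (may be empty).
#' @slot externalCalls data.frame with columns \code{snp}, \code{variable},
#'   \code{period}, \code{method}, \code{score}, \code{significant} (may have
#'   zero rows).
#' @export
setClass("GeaDataset",
  contains = "SummarizedExperiment",
  representation(
    climate = "matrix",
    pathways = "list",
    externalCalls = "data.frame"
  )
)

setValidity("GeaDataset", function(object) {
  msg <- NULL
  if (!"geno" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'geno' is required")
  cd <- SummarizedExperiment::colData(object)
  if (!"population" %in% colnames(cd))
    msg <- c(msg, "colData must contain a 'population' column")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("snp", "gene")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste0("rowData lacks column(s): ",
                         paste(miss, collapse = ", ")))
  if ("population" %in% colnames(cd) && nrow(object@climate) > 0L) {
    pops <- unique(as.character(cd$population))
    absent <- setdiff(pops, rownames(object@climate))
    if (length(absent))
      msg <- c(msg, paste0("populations missing from climate matrix: ",
                           paste(absent, collapse = ", ")))
  }
  if (nrow(object@externalCalls) > 0L) {
    needE <- c("snp", "variable", "period", "method", "score", "significant")
    missE <- setdiff(needE, colnames(object@externalCalls))
    if (length(missE))
      msg <- c(msg, paste0("externalCalls lacks column(s): ",
                           paste(missE, collapse = ", ")))
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a GeaDataset
#'
#' @param genotypes integer SNP x sample matrix of minor-allele copy counts
#'   (0/1/2, \code{NA} missing). Row names are SNP ids, column names sample
#'   ids.
#' @param snpMeta data.frame of per-SNP metadata; must contain \code{snp} and
#'   \code{gene}; typically also \code{pos}, \code{ref}, \code{alt},
#'   \code{coverage}, \code{alleleBalance}, \code{siteClass}.
#' @param popmap named character vector, sample id -> population label, or a
#'   data.frame with columns \code{sample}, \code{population}.
#' @param climate optional population x climate-column matrix (columns named
#'   \code{"<variable>_<period>"}).
#' @param pathways optional named list of gene-id vectors (or a
#'   [PathwayCollection-class]).
#' @param externalCalls optional data.frame of external association calls.
#' @return a [GeaDataset-class].
#' @export
GeaDataset <- function(genotypes, snpMeta, popmap,
                       climate = matrix(numeric(0), 0, 0),
                       pathways = list(),
                       externalCalls = data.frame()) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.data.frame(popmap))
    popmap <- setNames(as.character(popmap$population),
                       as.character(popmap$sample))
  absent <- setdiff(colnames(genotypes), names(popmap))
  if (length(absent))
    stop("sample(s) absent from popmap: ", paste(absent, collapse = ", "))
  if (is.null(rownames(genotypes))) rownames(genotypes) <- snpMeta$snp
  cd <- S4Vectors::DataFrame(
    population = unname(popmap[colnames(genotypes)]),
    row.names = colnames(genotypes))
  if (is(pathways, "PathwayCollection")) pathways <- pathways@sets
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(geno = genotypes),
    rowData = S4Vectors::DataFrame(snpMeta, row.names = snpMeta$snp),
    colData = cd)
  new("GeaDataset", se, climate = climate, pathways = pathways,
      externalCalls = externalCalls)
}

#' Genotype matrix accessor
#' @param x a [GeaDataset-class].
#' @return integer SNP x sample matrix of minor-allele copy counts.
#' @export
genotypes <- function(x) SummarizedExperiment::assay(x, "geno")

#' Per-SNP metadata accessor
#' @param x a [GeaDataset-class].
#' @return data.frame of per-SNP metadata.
#' @export
snpMeta <- function(x)
  as.data.frame(SummarizedExperiment::rowData(x))

#' Sample-to-population map accessor
#' @param x a [GeaDataset-class].
#' @return named character vector, sample id -> population label.
#' @export
popmap <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  setNames(as.character(cd$population), rownames(cd))
}

#' Climate matrix accessor
#' @param x a [GeaDataset-class].
#' @return numeric population x climate-column matrix.
#' @export
climateMatrix <- function(x) x@climate

#' External association-call table accessor
#' @param x a [GeaDataset-class].
#' @return data.frame of external SNP-level calls.
#' @export
externalCalls <- function(x) x@externalCalls

setMethod("show", "GeaDataset", function(object) {
  g <- genotypes(object)
  cat("GeaDataset: ", nrow(g), " SNPs x ", ncol(g), " samples (",
      length(unique(popmap(object))), " populations)\n", sep = "")
  cat("  genes: ", length(unique(snpMeta(object)$gene)),
      "; climate columns: ", ncol(object@climate),
      "; pathways: ", length(object@pathways),
      "; external calls: ", nrow(object@externalCalls), "\n", sep = "")
})
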