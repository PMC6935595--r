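## Seasonal climate aggregation, calibrated (range-normalized) Gower
## distance between climate vectors, and population-mean trait--climate
## correlations.

#' Aggregate monthly climate records into seasonal means
#'
#' Seasons are fixed as winter (December-February), spring (March-May),
#' summer (June-August) and fall (September-November); every seasonal value
#' is the arithmetic mean of its three months. December is taken from the
#' same record year as January and February (calendar-year convention,
#' recorded in the output's \code{"convention"} attribute).
#'
#' @param monthly data.frame or matrix with 12 rows (months, January
#'   first) and one column per variable, or a numeric vector of length 12.
#' @return matrix with rows \code{winter}, \code{spring}, \code{summer},
#'   \code{fall} and the input's variable columns.
#' @examples
#' seasonalAggregate(c(0, 2, 4, rep(10, 9)))["winter", ]  # mean(Dec,0,2)
#' @export
seasonalAggregate <- function(monthly) {
  m <- as.matrix(monthly)
  if (nrow(m) == 1L) m <- t(m)
  if (nrow(m) != 12L)
    stop("expected 12 monthly values, got ", nrow(m),
         if (nrow(m) < 12L) paste0(" (month ", nrow(m) + 1L, " missing)"))
  if (anyNA(m)) {
    bad <- which(apply(m, 1, anyNA))
    stop("missing value for month ", paste(month.name[bad], collapse = ", "))
  }
  seasons <- list(winter = c(12L, 1L, 2L), spring = 3:5, summer = 6:8,
                  fall = 9:11)
  out <- do.call(rbind, lapply(seasons, function(idx)
    colMeans(m[idx, , drop = FALSE])))
  dimnames(out) <- list(names(seasons), colnames(m))
  attr(out, "convention") <- "calendar-year (December of the same year)"
  out
}

#' Calibrated (range-normalized) Gower distance between climate vectors
#'
#' The mean over variables of \eqn{|source_v - garden_v| / range_v}, where
#' \code{ranges} holds each variable's observed range across the sites
#' being compared. Zero-range variables carry no information and are
#' dropped with a warning. The distance is symmetric, and lies in [0, 1]
#' whenever the deviations do not exceed the calibration ranges.
#'
#' @param source,garden numeric vectors of per-variable values.
#' @param ranges numeric vector of per-variable observed ranges; when
#'   omitted, ranges are computed from the two vectors themselves (rarely
#'   what you want; supply ranges over all source sites plus the garden).
#' @return scalar distance.
#' @export
gowerDistance <- function(source, garden, ranges = NULL) {
  stopifnot(length(source) == length(garden))
  if (is.null(ranges)) ranges <- abs(source - garden)
  stopifnot(length(ranges) == length(source))
  keep <- ranges > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " zero-range variable(s)")
    source <- source[keep]; garden <- garden[keep]; ranges <- ranges[keep]
  }
  if (!length(source)) return(NA_real_)
  mean(abs(source - garden) / ranges)
}

#' Correlate population trait means with climate variables
#'
#' Pearson correlation of population-level trait means with each climate
#' variable, with a two-sided t-test p-value; supports excluding
#' populations (e.g. those with too few genets) for sensitivity re-runs.
#'
#' @param traits named numeric vector of population trait means.
#' @param climate matrix or data.frame of climate values with populations
#'   as rows (a single vector is also accepted).
#' @param exclude population names to drop before correlating.
#' @return data.frame with one row per climate variable: \code{variable},
#'   \code{r}, \code{p}, \code{m} (populations used). Degenerate inputs
#'   (fewer than 4 shared populations or zero variance) give \code{NA}.
#' @export
traitClimateCorrelation <- function(traits, climate, exclude = character()) {
  cl <- as.matrix(climate)
  if (ncol(cl) == 1L && is.null(colnames(cl))) colnames(cl) <- "climate"
  pops <- intersect(names(traits), rownames(cl))
  pops <- setdiff(pops, exclude)
  rows <- lapply(colnames(cl), function(v) {
    x <- traits[pops]; y <- cl[pops, v]
    ok <- !is.na(x) & !is.na(y)
    m <- sum(ok)
    if (m < 4 || var(x[ok]) == 0 || var(y[ok]) == 0)
      return(data.frame(variable = v, r = NA_real_, p = NA_real_, m = m))
    r <- cor(x[ok], y[ok])
    p <- if (abs(r) >= 1 - 1e-12) 0 else
      2 * pt(abs(r) * sqrt((m - 2) / (1 - r^2)), m - 2, lower.tail = FALSE)
    data.frame(variable = v, r = r, p = p, m = m)
  })
  do.call(rbind, rows)
}
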