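#' Summary statistics of a response map
#'
#' Each orientation-pooled response map is reduced to three generalising
#' statistics of its value distribution: the arithmetic mean, the histogram
#' skewness (third central moment over the cube of the population standard
#' deviation, both with the 1/(mn) normalisation), and the Shannon entropy
#' in bits of the map's value histogram.
#'
#' All three are histogram functionals: permuting pixel positions within a
#' map leaves them unchanged.
#'
#' @param map numeric matrix (or vector) of response values.
#' @param bins number of equal-width histogram bins for the entropy,
#'   spanning the map's own \code{[min, max]} range (default 256; response
#'   scales differ by orders of magnitude across filter triples, so a fixed
#'   global range would be meaningless).
#' @return a scalar.
#' @name mapStatistics
NULL

#' @rdname mapStatistics
#' @export
mapMean <- function(map) {
  stopifnot(length(map) > 0)
  mean(map)
}

#' @rdname mapStatistics
#' @details \code{mapSkewness} of a zero-spread (constant) map is undefined;
#'   by convention 0 is returned with a warning so degenerate inputs do not
#'   abort batch runs.
#' @export
mapSkewness <- function(map) {
  stopifnot(length(map) > 0)
  m <- mean(map)
  s2 <- mean((map - m)^2)
  if (s2 == 0) {
    warning("zero-spread map: skewness undefined, returning 0")
    return(0)
  }
  mean((map - m)^3) / s2^1.5
}

#' @rdname mapStatistics
#' @export
mapEntropy <- function(map, bins = 256L) {
  stopifnot(length(map) > 0, bins >= 2L)
  lo <- min(map); hi <- max(map)
  if (lo == hi) return(0)
  breaks <- seq(lo, hi, length.out = bins + 1L)
  counts <- tabulate(.bincode(as.vector(map), breaks, include.lowest = TRUE),
                     nbins = bins)
  p <- counts[counts > 0] / length(map)
  -sum(p * log2(p))
}

#' Extract the feature vector of a response stack
#'
#' Applies [mapMean()], [mapSkewness()] and [mapEntropy()] to every pooled
#' map, yielding the per-cutout feature vector: one
#' \code{(mean, skew, entropy)} triplet per \eqn{(b, \lambda, \gamma)}
#' triple in canonical bank order — 108 values for the default bank.
#' Features are emitted raw; any centring or standardisation is the
#' severity model's concern.
#'
#' @param stack a [ResponseStack-class].
#' @param bins histogram bins for the entropy (default 256).
#' @return named numeric vector of length \code{3 * nMaps}.
#' @export
extractFeatures <- function(stack, bins = 256L) {
  stopifnot(is(stack, "ResponseStack"))
  maps <- responseMaps(stack)
  idx <- mapIndex(stack)
  if (length(maps) != nrow(idx))
    stop("response stack is inconsistent: map count != index rows")
  vals <- unlist(lapply(maps, function(m)
    c(mapMean(m), mapSkewness(m), mapEntropy(m, bins))))
  base <- sprintf("b%g_lam%g_gam%g", idx$bandwidth, idx$lambda, idx$gamma)
  names(vals) <- as.vector(t(outer(base, c("mean", "skew", "entropy"),
                                   paste, sep = "_")))
  vals
}

#' Feature matrix for a cohort of cutouts
#'
#' Full feature-extraction pipeline: convolve each cutout with the bank
#' (kernel spectra computed once), max-pool over orientation, and summarise
#' every pooled map, producing the cutouts x features matrix that
#' [fitSeverityModel()] consumes (n x 108 for the default bank).
#'
#' @param cutouts named list of 512 x 512 matrices (names become row names),
#'   e.g. the \code{cutouts} element of [generateCohort()].
#' @param bank a [GaborBank-class] (default: the standard 216-filter bank).
#' @param bins entropy histogram bins (default 256).
#' @param pool orientation pooling mode, see [orientationMax()].
#' @param verbose print a progress line per cutout.
#' @return numeric matrix, one row per cutout, one column per feature.
#' @export
extractFeatureMatrix <- function(cutouts, bank = buildGaborBank(),
                                 bins = 256L, pool = "signed",
                                 verbose = FALSE) {
  if (is.matrix(cutouts)) cutouts <- list(cutouts)
  pool <- match.arg(pool, c("signed", "magnitude"))
  size <- nrow(cutouts[[1]])
  # kernel spectra computed once; one cutout's maps in memory at a time
  sp <- .bankSpectra(gaborKernels(bank), size, size)
  idx <- .bankMapIndex(bank)
  nOri <- length(bankGrid(bank)$theta)
  rows <- lapply(seq_along(cutouts), function(i) {
    if (verbose)
      message(sprintf("features %d/%d", i, length(cutouts)))
    maps <- .pooledResponses(cutouts[[i]], sp, nOri, nrow(idx), pool)
    st <- new("ResponseStack", maps = maps, index = idx, cutoutId = "")
    extractFeatures(st, bins)
  })
  X <- do.call(rbind, rows)
  rownames(X) <- if (!is.null(names(cutouts))) names(cutouts) else
    sprintf("cutout_%03d", seq_along(cutouts))
  X
}

#' Write / read a feature matrix as CSV
#'
#' One row per cutout with a leading \code{cutout_id} column; feature
#' columns carry the canonical \code{b*_lam*_gam*_{mean|skew|entropy}}
#' names.
#'
#' @param X feature matrix with row names.
#' @param path CSV file path.
#' @return \code{readFeatureMatrix} returns the matrix with row names.
#' @export
writeFeatureMatrix <- function(X, path) {
  df <- data.frame(cutout_id = rownames(X), X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  X <- as.matrix(df[, setdiff(names(df), "cutout_id"), drop = FALSE])
  rownames(X) <- df$cutout_id
  X
}
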