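#' @import methods
NULL

#' GaborBank: an ordered bank of 2-D Gabor kernels
#'
#' Holds the discretised kernels for every combination of orientation
#' \eqn{\theta}, spatial aspect ratio \eqn{\gamma}, wavelength \eqn{\lambda}
#' (pixels) and half-response spatial-frequency bandwidth \eqn{b} (octaves).
#' The canonical ordering is fixed: bandwidth varies slowest, then wavelength,
#' then aspect ratio, with orientation innermost, so that the 6 orientations
#' of one \eqn{(b, \lambda, \gamma)} triple are contiguous.  Feature indices
#' downstream depend on this ordering; it is stamped into the
#' \code{orderingVersion} slot and serialised with the bank.
#'
#' @slot grid named list with numeric vectors \code{theta} (degrees),
#'   \code{gamma}, \code{lambda} (pixels), \code{bandwidth} (octaves) and the
#'   scalar \code{phi} (degrees).
#' @slot params data.frame with one row per kernel in canonical order:
#'   columns \code{bandwidth}, \code{lambda}, \code{gamma}, \code{theta},
#'   \code{phi}, \code{sigma} (pixels, derived from \code{bandwidth} and
#'   \code{lambda}).
#' @slot kernels list of numeric matrices (odd side length) in the same order.
#' @slot orderingVersion character tag identifying the ordering convention.
#'
#' @seealso [buildGaborBank()], [applyBank()], [responseStack()]
#' @export
setClass("GaborBank",
  representation(
    grid = "list",
    params = "data.frame",
    kernels = "list",
    orderingVersion = "character"
  )
)

setValidity("GaborBank", function(object) {
  g <- object@grid
  msg <- character(0)
  need <- c("theta", "gamma", "lambda", "bandwidth", "phi")
  if (!all(need %in% names(g)))
    msg <- c(msg, "grid must contain theta, gamma, lambda, bandwidth, phi")
  nExp <- length(g$theta) * length(g$gamma) * length(g$lambda) *
    length(g$bandwidth)
  if (length(object@kernels) != nExp)
    msg <- c(msg, sprintf("bank holds %d kernels, grid implies %d",
                          length(object@kernels), nExp))
  if (nrow(object@params) != length(object@kernels))
    msg <- c(msg, "params rows must match number of kernels")
  odd <- vapply(object@kernels, function(k) all(dim(k) %% 2L == 1L), logical(1))
  if (!all(odd)) msg <- c(msg, "all kernels must have odd side lengths")
  fin <- vapply(object@kernels, function(k) all(is.finite(k)), logical(1))
  if (!all(fin)) msg <- c(msg, "kernel weights must be finite")
  if (length(msg)) msg else TRUE
})

#' ResponseStack: orientation-pooled Gabor response maps for one cutout
#'
#' The elementwise maximum over the orientations of the bank, one map per
#' \eqn{(b, \lambda, \gamma)} triple (36 maps for the default bank).
#'
#' @slot maps list of numeric matrices, one per triple, in canonical bank
#'   order (bandwidth slowest, then wavelength, then aspect ratio).
#' @slot index data.frame with columns \code{bandwidth}, \code{lambda},
#'   \code{gamma}, one row per map.
#' @slot cutoutId character identifier of the source cutout.
#'
#' @seealso [orientationMax()], [responseStack()], [extractFeatures()]
#' @export
setClass("ResponseStack",
  representation(
    maps = "list",
    index = "data.frame",
    cutoutId = "character"
  )
)

setValidity("ResponseStack", function(object) {
  msg <- character(0)
  if (length(object@maps) != nrow(object@index))
    msg <- c(msg, "number of maps must match index rows")
  if (length(object@maps)) {
    d <- dim(object@maps[[1]])
    same <- vapply(object@maps, function(m) identical(dim(m), d), logical(1))
    if (!all(same)) msg <- c(msg, "all maps must share the same dimensions")
  }
  if (length(msg)) msg else TRUE
})

#' SeverityModel: PCA-based continuous severity score
#'
#' The eigendecomposition of the (optionally centred / standardised)
#' feature scatter matrix of a training cohort, together with everything
#' needed to project new cutouts onto the first principal component and
#' min-max normalise the projection to [0, 1].
#'
#' @slot eigenvectors m x m orthonormal matrix, columns sorted by descending
#'   eigenvalue.
#' @slot eigenvalues length-m nonnegative vector, descending.
#' @slot center length-m vector of training feature means (zeros when
#'   centring was disabled).
#' @slot scale length-m vector of per-feature scales (ones when
#'   standardisation was disabled).
#' @slot sign +1 or -1; orientation of the first eigenvector so that larger
#'   scores mean more severe inflammation.
#' @slot pc1Range training-set range of the oriented raw PC1 projection,
#'   \code{c(min, max)}; scores are \code{(pc1 - min) / (max - min)} clipped
#'   to [0, 1].
#' @slot featureNames character vector naming the features in bank order.
#' @slot centering,standardize logicals recording the fit configuration.
#'
#' @seealso [fitSeverityModel()], [severityScore()], [contributions()]
#' @export
setClass("SeverityModel",
  representation(
    eigenvectors = "matrix",
    eigenvalues = "numeric",
    center = "numeric",
    scale = "numeric",
    sign = "numeric",
    pc1Range = "numeric",
    featureNames = "character",
    centering = "logical",
    standardize = "logical"
  )
)

setValidity("SeverityModel", function(object) {
  msg <- character(0)
  m <- ncol(object@eigenvectors)
  if (nrow(object@eigenvectors) != m)
    msg <- c(msg, "eigenvector matrix must be square")
  if (length(object@eigenvalues) != m)
    msg <- c(msg, "eigenvalues length must match eigenvector columns")
  if (is.unsorted(rev(object@eigenvalues), strictly = FALSE))
    msg <- c(msg, "eigenvalues must be sorted in descending order")
  dev <- max(abs(crossprod(object@eigenvectors) - diag(m)))
  if (dev > 1e-8)
    msg <- c(msg, sprintf("eigenvectors not orthonormal (max dev %.2e)", dev))
  if (!object@sign %in% c(-1, 1))
    msg <- c(msg, "sign must be +1 or -1")
  if (length(object@pc1Range) != 2 || !(object@pc1Range[2] > object@pc1Range[1]))
    msg <- c(msg, "pc1Range must be c(min, max) with max > min")
  if (length(object@featureNames) != m)
    msg <- c(msg, "featureNames length must match number of features")
  if (length(msg)) msg else TRUE
})

#' @describeIn GaborBank-class compact summary of the bank grid
#' @param object a \code{GaborBank}
#' @export
setMethod("show", "GaborBank", function(object) {
  g <- object@grid
  cat("GaborBank with", length(object@kernels), "kernels\n")
  cat("  theta (deg):    ", paste(g$theta, collapse = ", "), "\n")
  cat("  gamma:          ", paste(g$gamma, collapse = ", "), "\n")
  cat("  lambda (px):    ", paste(g$lambda, collapse = ", "), "\n")
  cat("  bandwidth (oct):", paste(g$bandwidth, collapse = ", "), "\n")
  cat("  phi (deg):      ", g$phi, "\n")
  sides <- vapply(object@kernels, nrow, integer(1))
  cat("  kernel sides:    ", min(sides), "-", max(sides), "px\n", sep = "")
  cat("  ordering:        ", object@orderingVersion, "\n", sep = "")
})

#' @describeIn ResponseStack-class compact summary of the pooled maps
#' @param object a \code{ResponseStack}
#' @export
setMethod("show", "ResponseStack", function(object) {
  d <- if (length(object@maps)) dim(object@maps[[1]]) else c(0L, 0L)
  cat("ResponseStack:", length(object@maps), "orientation-pooled maps of",
      d[1], "x", d[2], "\n")
  if (nzchar(object@cutoutId)) cat("  cutout:", object@cutoutId, "\n")
})

#' @describeIn SeverityModel-class fit summary with leading variance fractions
#' @param object a \code{SeverityModel}
#' @export
setMethod("show", "SeverityModel", function(object) {
  m <- length(object@eigenvalues)
  vf <- varianceFraction(object, seq_len(min(3L, m)))
  cat("SeverityModel on", m, "features\n")
  cat("  centring:", object@centering, " standardised:", object@standardize, "\n")
  cat(sprintf("  PC1 variance fraction: %.1f%%", 100 * vf[1]), "\n")
  if (m >= 3)
    cat(sprintf("  PC2, PC3: %.1f%%, %.1f%%", 100 * vf[2], 100 * vf[3]), "\n")
  cat(sprintf("  raw PC1 training range: [%.4g, %.4g]\n",
              object@pc1Range[1], object@pc1Range[2]))
})
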