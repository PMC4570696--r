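#' Accessors for GaborBank, ResponseStack and SeverityModel
#'
#' Small read-only accessors so user code never touches slots directly.
#'
#' @param x a \code{GaborBank}, \code{ResponseStack} or \code{SeverityModel}
#' @return \code{gaborKernels}: list of kernel matrices in canonical order.
#'   \code{bankParams}: data.frame of per-kernel parameters.
#'   \code{bankGrid}: the four parameter lists plus \code{phi}.
#'   \code{nKernels}: number of kernels.
#'   \code{responseMaps}: list of pooled response matrices.
#'   \code{mapIndex}: data.frame of \code{(bandwidth, lambda, gamma)} per map.
#'   \code{eigenvalues} / \code{eigenvectors}: the sorted eigendecomposition.
#'   \code{featureNames}: feature labels in bank order.
#' @name accessors
NULL

#' @rdname accessors
#' @export
gaborKernels <- function(x) {
  stopifnot(is(x, "GaborBank"))
  x@kernels
}

#' @rdname accessors
#' @export
bankParams <- function(x) {
  stopifnot(is(x, "GaborBank"))
  x@params
}

#' @rdname accessors
#' @export
bankGrid <- function(x) {
  stopifnot(is(x, "GaborBank"))
  x@grid
}

#' @rdname accessors
#' @export
nKernels <- function(x) {
  stopifnot(is(x, "GaborBank"))
  length(x@kernels)
}

#' @rdname accessors
#' @export
responseMaps <- function(x) {
  stopifnot(is(x, "ResponseStack"))
  x@maps
}

#' @rdname accessors
#' @export
mapIndex <- function(x) {
  stopifnot(is(x, "ResponseStack"))
  x@index
}

#' @rdname accessors
#' @export
eigenvalues <- function(x) {
  stopifnot(is(x, "SeverityModel"))
  x@eigenvalues
}

#' @rdname accessors
#' @export
eigenvectors <- function(x) {
  stopifnot(is(x, "SeverityModel"))
  x@eigenvectors
}

#' @rdname accessors
#' @export
featureNames <- function(x) {
  stopifnot(is(x, "SeverityModel"))
  x@featureNames
}
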