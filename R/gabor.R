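## Gabor kernel construction.
##
## g(x, y) = exp(-(x'^2 + gamma^2 y'^2) / (2 sigma^2)) * cos(2 pi x'/lambda + phi)
## with x' = x cos(theta) + y sin(theta), y' = -x sin(theta) + y cos(theta).
## The envelope width sigma is tied to the wavelength through the
## half-response spatial-frequency bandwidth b (octaves):
##   sigma/lambda = (1/pi) * (sqrt(ln 2)/2) * (2^b + 1) / (2^b - 1)
## Note: a widely used variant of this relation has sqrt(ln2 / 2) in place of
## sqrt(ln 2)/2; this package implements the form above throughout, so the
## conversion and its inverse are mutually consistent.

.HALF_LN2 <- sqrt(log(2)) / 2

#' Convert frequency bandwidth (octaves) to the sigma/lambda ratio
#'
#' @param b half-response spatial-frequency bandwidth in octaves (> 0).
#' @return the dimensionless ratio \eqn{\sigma/\lambda}.
#' @seealso [sigmaRatioToBandwidth()] for the inverse.
#' @examples
#' bandwidthToSigmaRatio(5)   # ~0.14105
#' bandwidthToSigmaRatio(20)  # ~0.13251, near the large-b limit
#' @export
bandwidthToSigmaRatio <- function(b) {
  if (any(b <= 0)) stop("bandwidth must be positive (octaves)")
  (1 / pi) * .HALF_LN2 * (2^b + 1) / (2^b - 1)
}

#' Convert the sigma/lambda ratio to frequency bandwidth (octaves)
#'
#' Exact algebraic inverse of [bandwidthToSigmaRatio()].  The ratio must
#' exceed the large-bandwidth limit \eqn{(1/\pi)\sqrt{\ln 2}/2 \approx
#' 0.13251}, below which no finite bandwidth exists.
#'
#' @param ratio the dimensionless ratio \eqn{\sigma/\lambda}.
#' @return bandwidth in octaves.
#' @export
sigmaRatioToBandwidth <- function(ratio) {
  pole <- .HALF_LN2 / pi
  if (any(ratio <= pole))
    stop(sprintf("sigma/lambda ratio must exceed %.6f", pole))
  log2((ratio * pi + .HALF_LN2) / (ratio * pi - .HALF_LN2))
}

#' Construct one Gabor kernel
#'
#' Samples the Gabor function on an integer grid centred at the origin.  The
#' support half-width is \code{ceiling(3 * max(sigma, sigma/gamma))} so the
#' Gaussian envelope is truncated at three standard deviations along its
#' widest axis (for \code{gamma < 1} the envelope is wider along y').
#' Matrix rows index y (downwards) and columns index x, so
#' \code{weights[i, j] = g(x = j - c, y = i - c)} with c the centre index.
#'
#' @param lambda wavelength of the cosine carrier, pixels (> 0).
#' @param theta orientation, degrees.
#' @param gamma spatial aspect ratio of the Gaussian envelope (> 0).
#' @param bandwidth half-response spatial-frequency bandwidth, octaves (> 0);
#'   ignored when \code{sigma} is given directly.
#' @param phi phase offset of the carrier, degrees (default 0).
#' @param sigma Gaussian envelope standard deviation, pixels; by default
#'   derived from \code{bandwidth} and \code{lambda}.
#' @return numeric matrix of odd side length with attribute \code{params}
#'   (named list of the kernel parameters, including the derived sigma).
#' @examples
#' k <- gaborKernel(lambda = 20, theta = 0, gamma = 0.5, bandwidth = 5)
#' dim(k)  # odd side
#' @export
gaborKernel <- function(lambda, theta, gamma, bandwidth = NULL, phi = 0,
                        sigma = NULL) {
  stopifnot(lambda > 0, gamma > 0)
  if (is.null(sigma)) {
    if (is.null(bandwidth))
      stop("either bandwidth or sigma must be supplied")
    sigma <- bandwidthToSigmaRatio(bandwidth) * lambda
  }
  half <- ceiling(3 * max(sigma, sigma / gamma))
  off <- -half:half
  x <- matrix(off, nrow = length(off), ncol = length(off), byrow = TRUE)
  y <- matrix(off, nrow = length(off), ncol = length(off))
  th <- theta * pi / 180
  ph <- phi * pi / 180
  xp <- x * cos(th) + y * sin(th)
  yp <- -x * sin(th) + y * cos(th)
  w <- exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2)) *
    cos(2 * pi * xp / lambda + ph)
  attr(w, "params") <- list(lambda = lambda, theta = theta, gamma = gamma,
                            bandwidth = bandwidth, phi = phi, sigma = sigma)
  w
}

#' Default Gabor bank parameter grid
#'
#' Six orientations (0-150 degrees in 30-degree steps), aspect ratios
#' \{0.5, 2, 4\}, wavelengths \{20, 30, 40\} pixels, bandwidths
#' \{5, 10, 15, 20\} octaves and zero phase: 216 filters.  At such wide
#' bandwidths the ratio \eqn{\sigma/\lambda} is nearly constant
#' (0.14105 at b = 5 down to the 0.13251 limit), i.e. the four bandwidths
#' produce closely similar envelopes by design of the source protocol.
#'
#' @return named list with \code{theta}, \code{gamma}, \code{lambda},
#'   \code{bandwidth}, \code{phi}.
#' @export
defaultGaborGrid <- function() {
  list(theta = c(0, 30, 60, 90, 120, 150),
       gamma = c(0.5, 2, 4),
       lambda = c(20, 30, 40),
       bandwidth = c(5, 10, 15, 20),
       phi = 0)
}

#' Build a Gabor filter bank from a parameter grid
#'
#' Takes the Cartesian product of the four parameter lists in the canonical
#' order (bandwidth slowest, then wavelength, then aspect ratio, orientation
#' innermost) and constructs one kernel per combination.  With the default
#' grid this yields 216 kernels in 36 orientation groups of 6.
#'
#' @param theta orientations, degrees.
#' @param gamma spatial aspect ratios.
#' @param lambda wavelengths, pixels.
#' @param bandwidth frequency bandwidths, octaves.
#' @param phi scalar phase offset, degrees.
#' @return a [GaborBank-class] object.
#' @examples
#' bank <- buildGaborBank()
#' nKernels(bank)  # 216
#' @export
buildGaborBank <- function(theta = defaultGaborGrid()$theta,
                           gamma = defaultGaborGrid()$gamma,
                           lambda = defaultGaborGrid()$lambda,
                           bandwidth = defaultGaborGrid()$bandwidth,
                           phi = 0) {
  if (!length(theta) || !length(gamma) || !length(lambda) || !length(bandwidth))
    stop("every parameter list must be nonempty")
  params <- expand.grid(theta = theta, gamma = gamma, lambda = lambda,
                        bandwidth = bandwidth, KEEP.OUT.ATTRS = FALSE)
  params$phi <- phi
  params$sigma <- bandwidthToSigmaRatio(params$bandwidth) * params$lambda
  params <- params[, c("bandwidth", "lambda", "gamma", "theta", "phi", "sigma")]
  kernels <- lapply(seq_len(nrow(params)), function(i) {
    p <- params[i, ]
    gaborKernel(lambda = p$lambda, theta = p$theta, gamma = p$gamma,
                bandwidth = p$bandwidth, phi = p$phi)
  })
  new("GaborBank",
      grid = list(theta = theta, gamma = gamma, lambda = lambda,
                  bandwidth = bandwidth, phi = phi),
      params = params,
      kernels = kernels,
      orderingVersion = "b-lambda-gamma-theta/v1")
}

# The (bandwidth, lambda, gamma) triples in canonical order, one row per
# orientation group of the bank.
.bankMapIndex <- function(bank) {
  g <- bankGrid(bank)
  idx <- expand.grid(gamma = g$gamma, lambda = g$lambda,
                     bandwidth = g$bandwidth, KEEP.OUT.ATTRS = FALSE)
  idx[, c("bandwidth", "lambda", "gamma")]
}

#' Feature labels implied by a bank's canonical ordering
#'
#' One \code{b{b}_lam{lambda}_gam{gamma}_{mean|skew|entropy}} label per
#' feature, triplets in bank order.
#'
#' @param bank a [GaborBank-class].
#' @return character vector of length \code{3 * nMaps}.
#' @export
bankFeatureNames <- function(bank) {
  idx <- .bankMapIndex(bank)
  base <- sprintf("b%g_lam%g_gam%g", idx$bandwidth, idx$lambda, idx$gamma)
  as.vector(t(outer(base, c("mean", "skew", "entropy"), paste, sep = "_")))
}
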