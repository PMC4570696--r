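## FFT-based 2-D convolution with reflected (symmetric) boundary padding.
##
## True convolution is computed: response(x) = sum_t k(t) * img(x - t), i.e.
## the kernel is flipped relative to cross-correlation.  The image is padded
## by mirroring `half` pixels at each border (edge pixel repeated), embedded
## in a highly composite FFT size, and circular convolution on the padded
## array restricted to the valid region equals the reflect-padded linear
## convolution exactly.
##
## Because image and kernels are real, two kernels are packed into one
## complex transform (k1 + i k2): the real and imaginary parts of the
## inverse transform are the two response maps.  Kernel spectra are computed
## once per (bank, image size) and reused across cutouts.

.padReflect <- function(img, half) {
  nr <- nrow(img); nc <- ncol(img)
  if (half >= nr || half >= nc)
    stop("padding exceeds image size")
  ri <- c(half:1, 1:nr, nr:(nr - half + 1))
  ci <- c(half:1, 1:nc, nc:(nc - half + 1))
  img[ri, ci]
}

# Smallest 5-smooth integer >= n (good FFT sizes).
.goodFFTSize <- function(n) {
  m <- n
  repeat {
    k <- m
    for (p in c(2, 3, 5)) while (k %% p == 0) k <- k / p
    if (k == 1) return(m)
    m <- m + 1
  }
}

# Embed kernel in an N x N array with its centre wrapped to index (1, 1).
.embedKernel <- function(kernel, N) {
  half <- (nrow(kernel) - 1L) %/% 2L
  big <- matrix(0, N, N)
  idx <- ((-half:half) %% N) + 1L
  big[idx, idx] <- kernel
  big
}

# Precompute packed kernel spectra for an image of size nr x nc.
# Returns list(N, half, spectra, pairs) where spectra[[j]] is the FFT of
# kernel 2j-1 + i * kernel 2j (last one possibly unpaired).
.bankSpectra <- function(kernels, nr, nc) {
  halfs <- vapply(kernels, function(k) (nrow(k) - 1L) %/% 2L, integer(1))
  half <- max(halfs)
  N <- .goodFFTSize(max(nr, nc) + 2L * half)
  nk <- length(kernels)
  pairs <- split(seq_len(nk), ceiling(seq_len(nk) / 2))
  spectra <- lapply(pairs, function(p) {
    k1 <- .embedKernel(kernels[[p[1]]], N)
    pack <- if (length(p) == 2L)
      k1 + 1i * .embedKernel(kernels[[p[2]]], N) else k1
    fftwtools::fftw2d(pack)
  })
  list(N = N, half = half, spectra = spectra, pairs = pairs, nk = nk)
}

# Convolve one image against precomputed spectra; returns list of response
# matrices (same size as img) in kernel order.
.convolveWithSpectra <- function(img, sp) {
  nr <- nrow(img); nc <- ncol(img)
  padded <- .padReflect(img, sp$half)
  big <- matrix(0, sp$N, sp$N)
  big[seq_len(nrow(padded)), seq_len(ncol(padded))] <- padded
  F <- fftwtools::fftw2d(big)
  rows <- sp$half + seq_len(nr)
  cols <- sp$half + seq_len(nc)
  out <- vector("list", sp$nk)
  for (j in seq_along(sp$spectra)) {
    y <- fftwtools::fftw2d(F * sp$spectra[[j]], inverse = 1) / sp$N^2
    p <- sp$pairs[[j]]
    out[[p[1]]] <- Re(y)[rows, cols]
    if (length(p) == 2L) out[[p[2]]] <- Im(y)[rows, cols]
  }
  out
}

#' Convolve an image with a single kernel (reflect padding)
#'
#' True convolution (kernel flipped relative to correlation) with
#' symmetric-reflection boundary handling; output has the size of the input.
#' Used pervasively by [applyBank()]; exposed for testing and for probing
#' individual filters.
#'
#' @param img numeric matrix.
#' @param kernel numeric matrix of odd side length.
#' @return numeric matrix, same dimensions as \code{img}.
#' @export
convolveReflect <- function(img, kernel) {
  stopifnot(is.matrix(img), is.matrix(kernel), all(dim(kernel) %% 2L == 1L))
  sp <- .bankSpectra(list(kernel), nrow(img), ncol(img))
  .convolveWithSpectra(img, sp)[[1]]
}

#' Apply every filter of a bank to a cutout
#'
#' Convolves the 512 x 512 cutout with each kernel of the bank (reflect
#' padding, output same size).  With the default 216-filter bank the result
#' holds 216 maps; see [responseStack()] for the memory-friendlier pooled
#' pipeline.
#'
#' @param cutout numeric matrix, 512 x 512 unless \code{size} is changed.
#' @param bank a [GaborBank-class].
#' @param size expected cutout side length (default 512).
#' @return list of response matrices in canonical bank order.
#' @export
applyBank <- function(cutout, bank, size = 512L) {
  stopifnot(is(bank, "GaborBank"))
  if (!is.matrix(cutout) || nrow(cutout) != size || ncol(cutout) != size)
    stop(sprintf("cutout must be a %d x %d matrix", size, size))
  sp <- .bankSpectra(gaborKernels(bank), nrow(cutout), ncol(cutout))
  .convolveWithSpectra(cutout, sp)
}

#' Max-pool per-filter responses over orientation
#'
#' For each \eqn{(b, \lambda, \gamma)} triple, takes the elementwise maximum
#' of the signed responses across the bank's orientations, compensating the
#' arbitrary initial orientation of the tissue.  The default bank's 216 maps
#' reduce to 36.  Pooling of response magnitudes is available via
#' \code{pool = "magnitude"}.
#'
#' @param responses list of per-filter response matrices in canonical bank
#'   order (as returned by [applyBank()]).
#' @param bank the [GaborBank-class] that produced them.
#' @param pool \code{"signed"} (elementwise max of signed responses, the
#'   default) or \code{"magnitude"} (max of absolute responses).
#' @param cutoutId optional identifier stored in the result.
#' @return a [ResponseStack-class] with one map per triple.
#' @export
orientationMax <- function(responses, bank, pool = c("signed", "magnitude"),
                           cutoutId = "") {
  pool <- match.arg(pool)
  stopifnot(is(bank, "GaborBank"))
  nOri <- length(bankGrid(bank)$theta)
  if (length(responses) != nKernels(bank))
    stop(sprintf("expected %d response maps (one per kernel), got %d",
                 nKernels(bank), length(responses)))
  idx <- .bankMapIndex(bank)
  maps <- lapply(seq_len(nrow(idx)), function(g) {
    block <- responses[(g - 1L) * nOri + seq_len(nOri)]
    if (pool == "magnitude") block <- lapply(block, abs)
    Reduce(pmax, block)
  })
  new("ResponseStack", maps = maps, index = idx, cutoutId = cutoutId)
}

#' Orientation-pooled response stack for one or more cutouts
#'
#' Runs [applyBank()] and [orientationMax()] while keeping only one
#' orientation group of responses in memory at a time, and reuses the
#' kernel spectra across cutouts — the recommended entry point for cohorts.
#'
#' @param cutouts a single matrix or a (possibly named) list of matrices,
#'   each 512 x 512 unless \code{size} is changed.
#' @inheritParams orientationMax
#' @inheritParams applyBank
#' @return a [ResponseStack-class], or a list of them when \code{cutouts}
#'   is a list.
#' @export
responseStack <- function(cutouts, bank, pool = c("signed", "magnitude"),
                          size = 512L) {
  pool <- match.arg(pool)
  stopifnot(is(bank, "GaborBank"))
  single <- is.matrix(cutouts)
  if (single) cutouts <- list(cutouts)
  ok <- vapply(cutouts, function(x)
    is.matrix(x) && nrow(x) == size && ncol(x) == size, logical(1))
  if (!all(ok)) stop(sprintf("every cutout must be a %d x %d matrix", size, size))
  sp <- .bankSpectra(gaborKernels(bank), size, size)
  ids <- names(cutouts)
  if (is.null(ids)) ids <- rep("", length(cutouts))
  idx <- .bankMapIndex(bank)
  nOri <- length(bankGrid(bank)$theta)
  stacks <- lapply(seq_along(cutouts), function(i) {
    maps <- .pooledResponses(cutouts[[i]], sp, nOri, nrow(idx), pool)
    new("ResponseStack", maps = maps, index = idx, cutoutId = ids[i])
  })
  if (single) stacks[[1]] else stacks
}

# Streamed convolution + orientation pooling: one packed spectrum (two
# kernels) in flight at a time, pooled maps accumulated in place.
.pooledResponses <- function(img, sp, nOri, nGroups, pool) {
  nr <- nrow(img); nc <- ncol(img)
  padded <- .padReflect(img, sp$half)
  big <- matrix(0, sp$N, sp$N)
  big[seq_len(nrow(padded)), seq_len(ncol(padded))] <- padded
  F <- fftwtools::fftw2d(big)
  rows <- sp$half + seq_len(nr)
  cols <- sp$half + seq_len(nc)
  maps <- vector("list", nGroups)
  for (j in seq_along(sp$spectra)) {
    y <- fftwtools::fftw2d(F * sp$spectra[[j]], inverse = 1) / sp$N^2
    p <- sp$pairs[[j]]
    parts <- list(Re(y)[rows, cols])
    if (length(p) == 2L) parts[[2]] <- Im(y)[rows, cols]
    for (q in seq_along(p)) {
      g <- ceiling(p[q] / nOri)
      r <- if (pool == "magnitude") abs(parts[[q]]) else parts[[q]]
      maps[[g]] <- if (is.null(maps[[g]])) r else pmax(maps[[g]], r)
    }
  }
  maps
}
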