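#' Read a histology image as a grayscale intensity matrix
#'
#' Reads PNG or TIFF (8- or 16-bit, grayscale or RGB; an alpha channel is
#' dropped) and returns a numeric matrix of intensities in [0, 1].  Colour
#' images are reduced with [toGrayscale()].
#'
#' @param path path to a \code{.png}, \code{.tif} or \code{.tiff} file.
#' @return numeric matrix in [0, 1] with attribute \code{sourcePath}.
#' @export
readHistologyImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: '", ext, "' (PNG or TIFF expected)")
  )
  if (length(dim(arr)) == 3L && dim(arr)[3] == 4L)
    arr <- arr[, , 1:3, drop = FALSE]
  img <- toGrayscale(arr)
  attr(img, "sourcePath") <- path
  img
}

#' Convert an image array to grayscale intensities in [0, 1]
#'
#' Single-channel input is returned as a matrix (values are expected already
#' in [0, 1], as produced by the png/tiff readers, which divide by the bit
#' depth's maximum code value).  Three-channel input is reduced with the
#' Rec. 601 luminance weighting \eqn{0.299 R + 0.587 G + 0.114 B}.
#'
#' @param x numeric matrix (grayscale) or H x W x 3 array (RGB).
#' @return numeric matrix of intensities in [0, 1].
#' @examples
#' toGrayscale(array(c(1, 0, 0), dim = c(1, 1, 3)))  # pure red -> 0.299
#' @export
toGrayscale <- function(x) {
  if (is.matrix(x)) {
    img <- x
  } else if (length(dim(x)) == 3L && dim(x)[3] == 1L) {
    img <- x[, , 1]
  } else if (length(dim(x)) == 3L && dim(x)[3] == 3L) {
    img <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
  } else {
    stop("unsupported format: expected 1 or 3 channels, got dim ",
         paste(dim(x), collapse = "x"))
  }
  if (anyNA(img) || min(img) < 0 || max(img) > 1)
    stop("pixel intensities must lie in [0, 1]")
  img
}

# Fixed 256-bin histogram over [0, 1]; returns counts and bin centers.
.intensityHist <- function(img, bins = 256L) {
  breaks <- seq(0, 1, length.out = bins + 1L)
  idx <- .bincode(pmin(pmax(as.vector(img), 0), 1), breaks,
                  include.lowest = TRUE)
  counts <- tabulate(idx, nbins = bins)
  list(counts = counts,
       centers = (breaks[-1L] + breaks[-(bins + 1L)]) / 2,
       width = 1 / bins)
}

#' Locate the white-area peak of an image histogram
#'
#' Brightfield histology images contain empty (cell-free) regions whose
#' pixels form a peak on the right side of the intensity histogram.  This
#' returns the centre of the rightmost local maximum of the histogram whose
#' height exceeds 1\% of the modal bin height.
#'
#' @param img numeric matrix in [0, 1].
#' @param bins number of histogram bins (>= 16; default 256).
#' @return intensity value of the peak (bin centre).
#' @export
whitePeak <- function(img, bins = 256L) {
  stopifnot(length(img) > 0, bins >= 16L)
  h <- .intensityHist(img, bins)
  cnt <- h$counts
  n <- length(cnt)
  left <- c(-Inf, cnt[-n])
  right <- c(cnt[-1L], -Inf)
  isMax <- cnt >= left & cnt >= right & cnt > 0 & cnt > 0.01 * max(cnt)
  if (!any(isMax))
    stop("no white-region peak found in the image histogram")
  h$centers[max(which(isMax))]
}

#' Illumination bias aligning an image's white peak to a reference
#'
#' Determines the additive intensity bias that best aligns the white-area
#' histogram peak of \code{img} with that of \code{reference}, by grid
#' search: for each candidate bias the histogram of \code{img + bias} is
#' correlated with the reference histogram over a window around the
#' reference white peak (plus/minus \code{window} of the intensity range),
#' and the bias maximising the Pearson correlation is returned (ties broken
#' towards the smallest absolute bias).
#'
#' @param img,reference numeric matrices in [0, 1]; both must have a
#'   detectable white peak.
#' @param searchRange numeric length-2, bias interval searched
#'   (default \code{c(-0.2, 0.2)}).
#' @param step grid step of the search (default 1/512, half a bin width).
#' @param bins histogram bins (default 256).
#' @param window half-width of the correlation window around the reference
#'   peak, as a fraction of the intensity range (default 0.1).  Set
#'   \code{fullHistogram = TRUE} to correlate over the entire histogram
#'   instead.
#' @param fullHistogram logical; correlate full histograms rather than the
#'   white-peak window.
#' @return the bias (scalar), with attribute \code{correlation}.
#' @export
illuminationBias <- function(img, reference, searchRange = c(-0.2, 0.2),
                             step = 1 / 512, bins = 256L, window = 0.1,
                             fullHistogram = FALSE) {
  if (length(searchRange) != 2L || searchRange[2] < searchRange[1])
    stop("searchRange must be c(lo, hi) with hi >= lo")
  refPeak <- whitePeak(reference, bins)
  imgPeak <- whitePeak(img, bins)
  refHist <- .intensityHist(reference, bins)
  if (fullHistogram) {
    sel <- rep(TRUE, bins)
  } else {
    sel <- abs(refHist$centers - refPeak) <= window
  }
  refCounts <- refHist$counts[sel]
  # grid anchored at 0 so exact self-alignment is representable
  if (searchRange[1] <= 0 && searchRange[2] >= 0) {
    grid <- sort(unique(c(seq(0, searchRange[1], by = -step),
                          seq(0, searchRange[2], by = step))))
  } else {
    grid <- seq(searchRange[1], searchRange[2], by = step)
  }
  if (!fullHistogram) {
    # only biases that bring the image's own white peak into the window:
    # the alignment is between white-area peaks, not arbitrary histogram
    # content that a large shift might drag into the window
    grid <- grid[abs(imgPeak + grid - refPeak) <= window]
    if (!length(grid))
      stop("no white-region histogram content overlaps the reference peak ",
           "window within the search range")
  }
  score <- vapply(grid, function(b) {
    cnt <- .intensityHist(img + b, bins)$counts[sel]
    if (stats::sd(cnt) == 0 || stats::sd(refCounts) == 0) return(-Inf)
    stats::cor(cnt, refCounts)
  }, numeric(1))
  best <- max(score)
  if (!is.finite(best))
    stop("no white-region histogram content overlaps the reference peak ",
         "window within the search range")
  cand <- grid[score >= best - 1e-12]
  bias <- cand[which.min(abs(cand))]
  structure(bias, correlation = best)
}

#' Normalise illumination against a reference image
#'
#' Adds the bias found by [illuminationBias()] and clips to [0, 1] (the
#' adjustment is purely additive; no rescaling is performed).
#'
#' @inheritParams illuminationBias
#' @param ... passed on to [illuminationBias()].
#' @return the adjusted image, with attribute \code{bias}.
#' @export
normalizeIllumination <- function(img, reference, ...) {
  bias <- illuminationBias(img, reference, ...)
  out <- pmin(pmax(img + as.numeric(bias), 0), 1)
  attr(out, "bias") <- as.numeric(bias)
  attr(out, "sourcePath") <- attr(img, "sourcePath")
  out
}

#' Extract a 512 x 512 cutout from an image
#'
#' Cutout placement follows explicit coordinates (in the source study,
#' experts chose homogeneous tissue regions by hand).  Offsets are 0-based
#' from the top-left corner, matching the cutout coordinate CSV convention
#' (\code{image,row,col}).
#'
#' @param img numeric matrix (the full image).
#' @param row,col 0-based pixel offsets of the cutout's top-left corner.
#' @param size cutout side length in pixels (default 512).
#' @return \code{size} x \code{size} numeric matrix with attributes
#'   \code{originRow} and \code{originCol}.
#' @export
extractCutout <- function(img, row, col, size = 512L) {
  stopifnot(is.matrix(img), row >= 0, col >= 0)
  if (row + size > nrow(img) || col + size > ncol(img))
    stop(sprintf(
      "cutout out of bounds: origin (%d, %d) + %d exceeds image %d x %d",
      row, col, size, nrow(img), ncol(img)))
  out <- img[(row + 1L):(row + size), (col + 1L):(col + size)]
  attr(out, "originRow") <- as.integer(row)
  attr(out, "originCol") <- as.integer(col)
  out
}
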