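#' Serialise / restore a Gabor bank as JSON
#'
#' Only the parameter grid and the ordering version tag are stored; kernels
#' are rebuilt deterministically on read.
#'
#' @param bank a [GaborBank-class].
#' @param path JSON file path.
#' @return \code{readGaborBank} returns the rebuilt bank; an error is
#'   raised if the file's ordering convention is not understood.
#' @export
writeGaborBank <- function(bank, path) {
  stopifnot(is(bank, "GaborBank"))
  obj <- c(list(format = "gaborSeverity/bank/v1",
                ordering = bank@orderingVersion),
           bankGrid(bank))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeGaborBank
#' @export
readGaborBank <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "gaborSeverity/bank/v1"))
    stop("not a gaborSeverity bank file")
  if (!identical(obj$ordering, "b-lambda-gamma-theta/v1"))
    stop("unsupported bank ordering: ", obj$ordering)
  buildGaborBank(theta = obj$theta, gamma = obj$gamma, lambda = obj$lambda,
                 bandwidth = obj$bandwidth, phi = obj$phi)
}

#' Write a grayscale intensity matrix as PNG
#'
#' @param img numeric matrix in [0, 1].
#' @param path output path.
#' @export
writeGrayPNG <- function(img, path) {
  stopifnot(is.matrix(img), min(img) >= 0, max(img) <= 1)
  png::writePNG(img, path)
  invisible(path)
}
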