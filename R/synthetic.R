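## Synthetic HE-like cutout generator.
##
## Real cutouts show bright elliptic crypt cross-sections (about 180-350 px
## long and 50-130 px wide at 0.6 um/px) on a lighter stroma, with small
## dark round infiltrate spots (7-25 px across) appearing as inflammation
## develops.  A scalar latent severity in [0, 1] drives three morphological
## changes at once: crypt loss (count decreases linearly), crypt boundary
## irregularity (radial perturbation amplitude increases linearly), and
## infiltrate density (spot count increases linearly).

#' Specification of a synthetic histology-like cutout
#'
#' Bundles the generator parameters; [syntheticCutout()] accepts the same
#' arguments directly.  Defaults follow the morphology of HE-stained colon
#' mucosa at 0.6 um/pixel: crypt long axes 180-350 px, short axes
#' 50-130 px, infiltrate spot diameters 7-25 px.
#'
#' @param severity latent inflammation severity in [0, 1].
#' @param seed integer seed; the image is a deterministic function of the
#'   spec including the seed.
#' @param size cutout side, pixels (default 512).
#' @param backgroundLevel stroma intensity (default 0.75).
#' @param cryptLevel intensity of crypt interiors (default 0.95, brighter
#'   than stroma).
#' @param spotLevel intensity of infiltrate spots (default 0.35, dark).
#' @param cryptCountRange \code{c(min, max)} crypt counts; the realised
#'   count falls linearly from max (severity 0) to min (severity 1).
#' @param cryptLength,cryptWidth full-axis ranges in pixels.
#' @param spotDiameter spot diameter range in pixels.
#' @param spotDensityPerSeverity spots per pixel^2 per unit severity
#'   (default 5.7e-4, about 150 spots on a 512 x 512 cutout at severity 1).
#' @param irregularity \code{c(min, max)} radial boundary perturbation
#'   amplitude (fraction of the crypt radius), interpolated linearly in
#'   severity.
#' @param noiseSd standard deviation of additive Gaussian pixel noise
#'   (default 0.03).
#' @return named list of class \code{"syntheticSpec"}.
#' @export
syntheticSpec <- function(severity, seed = 1L, size = 512L,
                          backgroundLevel = 0.75, cryptLevel = 0.95,
                          spotLevel = 0.35, cryptCountRange = c(4L, 8L),
                          cryptLength = c(180, 350), cryptWidth = c(50, 130),
                          spotDiameter = c(7, 25),
                          spotDensityPerSeverity = 5.7e-4,
                          irregularity = c(0.05, 0.35), noiseSd = 0.03) {
  stopifnot(severity >= 0, severity <= 1, noiseSd >= 0,
            cryptCountRange[1] >= 0, cryptCountRange[2] >= cryptCountRange[1])
  structure(list(severity = severity, seed = as.integer(seed), size = size,
                 backgroundLevel = backgroundLevel, cryptLevel = cryptLevel,
                 spotLevel = spotLevel, cryptCountRange = cryptCountRange,
                 cryptLength = cryptLength, cryptWidth = cryptWidth,
                 spotDiameter = spotDiameter,
                 spotDensityPerSeverity = spotDensityPerSeverity,
                 irregularity = irregularity, noiseSd = noiseSd),
            class = "syntheticSpec")
}

# Paint one irregular ellipse (value `level`) onto img; boundary radius is
# modulated by a random low-order Fourier series of amplitude `amp`.
.paintCrypt <- function(img, cx, cy, a, b, angle, amp, fourier, level) {
  size <- nrow(img)
  reach <- ceiling(max(a, b) * (1 + amp) + 1)
  rows <- max(1, floor(cy - reach)):min(size, ceiling(cy + reach))
  cols <- max(1, floor(cx - reach)):min(size, ceiling(cx + reach))
  dy <- rows - cy
  dx <- cols - cx
  X <- matrix(dx, nrow = length(rows), ncol = length(cols), byrow = TRUE)
  Y <- matrix(dy, nrow = length(rows), ncol = length(cols))
  xr <- X * cos(angle) + Y * sin(angle)
  yr <- -X * sin(angle) + Y * cos(angle)
  u <- xr / a; v <- yr / b
  rho <- sqrt(u^2 + v^2)
  al <- atan2(v, u)
  mod <- 0
  for (h in seq_along(fourier$c))
    mod <- mod + fourier$c[h] * cos((h + 1) * al) +
      fourier$s[h] * sin((h + 1) * al)
  inside <- rho <= 1 + amp * mod
  img[rows, cols][inside] <- level
  img
}

#' Generate one synthetic histology-like cutout
#'
#' Renders stroma at \code{backgroundLevel}, bright crypt-like ellipses
#' with randomly perturbed boundaries, dark infiltrate-like discs, and
#' additive Gaussian noise, clipped to [0, 1].  The same spec (including
#' seed) always yields a bit-identical image; the realised object lists are
#' attached as ground truth.
#'
#' @param spec a [syntheticSpec()], or the \code{severity} value when the
#'   remaining arguments are given via \code{...}.
#' @param ... passed to [syntheticSpec()] when \code{spec} is a number.
#' @return \code{size} x \code{size} intensity matrix with attribute
#'   \code{truth}: a list with the spec and the realised \code{crypts}
#'   (centre, axes, orientation, irregularity) and \code{spots} (centre,
#'   radius) tables.
#' @examples
#' img <- syntheticCutout(0.5, seed = 7)
#' range(img)
#' @export
syntheticCutout <- function(spec, ...) {
  if (!inherits(spec, "syntheticSpec")) spec <- syntheticSpec(spec, ...)
  s <- spec
  .withSeed(s$seed, {
    img <- matrix(s$backgroundLevel, s$size, s$size)
    cr <- s$cryptCountRange
    nCrypt <- as.integer(round(cr[2] - s$severity * (cr[2] - cr[1])))
    amp <- s$irregularity[1] +
      s$severity * (s$irregularity[2] - s$irregularity[1])
    crypts <- NULL
    if (nCrypt > 0) {
      crypts <- data.frame(
        cx = stats::runif(nCrypt, 1, s$size),
        cy = stats::runif(nCrypt, 1, s$size),
        a = stats::runif(nCrypt, s$cryptLength[1], s$cryptLength[2]) / 2,
        b = stats::runif(nCrypt, s$cryptWidth[1], s$cryptWidth[2]) / 2,
        angle = stats::runif(nCrypt, 0, pi),
        amp = amp)
      for (i in seq_len(nCrypt)) {
        fourier <- list(c = stats::rnorm(4, sd = c(1, 0.7, 0.5, 0.35) / 2),
                        s = stats::rnorm(4, sd = c(1, 0.7, 0.5, 0.35) / 2))
        img <- .paintCrypt(img, crypts$cx[i], crypts$cy[i], crypts$a[i],
                           crypts$b[i], crypts$angle[i], amp, fourier,
                           s$cryptLevel)
      }
    }
    nSpot <- as.integer(round(s$spotDensityPerSeverity * s$severity * s$size^2))
    spots <- NULL
    if (nSpot > 0) {
      spots <- data.frame(cx = stats::runif(nSpot, 1, s$size),
                          cy = stats::runif(nSpot, 1, s$size),
                          r = stats::runif(nSpot, s$spotDiameter[1],
                                           s$spotDiameter[2]) / 2)
      for (i in seq_len(nSpot)) {
        reach <- ceiling(spots$r[i] + 1)
        rows <- max(1, floor(spots$cy[i] - reach)):
          min(s$size, ceiling(spots$cy[i] + reach))
        cols <- max(1, floor(spots$cx[i] - reach)):
          min(s$size, ceiling(spots$cx[i] + reach))
        D2 <- outer((rows - spots$cy[i])^2, (cols - spots$cx[i])^2, "+")
        img[rows, cols][D2 <= spots$r[i]^2] <- s$spotLevel
      }
    }
    if (s$noiseSd > 0)
      img <- img + matrix(stats::rnorm(s$size^2, sd = s$noiseSd),
                          s$size, s$size)
    img <- pmin(pmax(img, 0), 1)
    attr(img, "truth") <- list(spec = s, crypts = crypts, spots = spots,
                               nCrypts = nCrypt, nSpots = nSpot)
    img
  })
}

#' Generate a cohort of synthetic cutouts across severity levels
#'
#' Emulates a graded study design (e.g. healthy controls, chronic and acute
#' inflammation): \code{nPerLevel} cutouts at each latent severity level.
#' Per-cutout seeds are derived from the cohort seed by a counter scheme
#' (\code{(seed mod 2^20) * 1000 + i}), so cohorts are reproducible and any
#' cutout can be regenerated in isolation.
#'
#' @param nPerLevel cutouts per severity level.
#' @param levels numeric vector of latent severities in [0, 1]
#'   (default \code{c(0, 0.5, 1)}).
#' @param seed cohort seed.
#' @param ... further generator parameters passed to [syntheticSpec()].
#' @return list with \code{cutouts} (named list of matrices) and
#'   \code{truth} (data.frame: \code{cutout_id}, \code{severity},
#'   \code{seed}, \code{n_crypts}, \code{n_spots}).
#' @examples
#' coh <- generateCohort(2, levels = c(0, 1), seed = 11)
#' coh$truth
#' @export
generateCohort <- function(nPerLevel, levels = c(0, 0.5, 1), seed = 1L, ...) {
  stopifnot(length(levels) >= 1, nPerLevel >= 1)
  base <- (as.integer(seed) %% 2L^20L) * 1000L
  grid <- expand.grid(rep = seq_len(nPerLevel), severity = levels,
                      KEEP.OUT.ATTRS = FALSE)
  ids <- sprintf("s%0.2f_%03d", grid$severity, grid$rep)
  cutouts <- vector("list", nrow(grid))
  truth <- data.frame(cutout_id = ids, severity = grid$severity,
                      seed = base + seq_len(nrow(grid)),
                      n_crypts = NA_integer_, n_spots = NA_integer_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    img <- syntheticCutout(syntheticSpec(grid$severity[i],
                                         seed = truth$seed[i], ...))
    tr <- attr(img, "truth")
    truth$n_crypts[i] <- tr$nCrypts
    truth$n_spots[i] <- tr$nSpots
    cutouts[[i]] <- img
  }
  names(cutouts) <- ids
  list(cutouts = cutouts, truth = truth)
}
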