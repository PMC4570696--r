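#' Fit the PCA severity model on a training feature matrix
#'
#' Eigendecomposes the m x m feature scatter matrix
#' \eqn{S = X_c^T X_c / (n m)} of the (by default mean-centred) training
#' features and takes the first principal component as a continuous
#' severity axis.  The 1/(n m) normalisation only scales the eigenvalues;
#' variance fractions and scores are unaffected by it.
#'
#' The sign of an eigenvector is arbitrary.  When per-row ordinal severity
#' hints are supplied (e.g. 0 = control, 1 = chronic, 2 = acute) the first
#' eigenvector is oriented so raw PC1 correlates positively with them;
#' otherwise the orientation makes the largest-magnitude PC1 loading
#' positive.  The training-set range of the oriented raw PC1 defines the
#' min-max normalisation of [severityScore()], so training rows span
#' exactly [0, 1].
#'
#' Centring can be disabled (\code{center = FALSE}) to reproduce the
#' literal uncentred second-moment decomposition, in which PC1 largely
#' encodes the grand mean of the features; per-feature standardisation
#' (\code{standardize = TRUE}) is off by default since the raw feature
#' scales are part of the method.
#'
#' @param X numeric matrix, cutouts x features, no missing values, n >= 2.
#' @param center logical, subtract training feature means (default TRUE).
#' @param standardize logical, divide by training feature standard
#'   deviations (default FALSE).
#' @param labels optional numeric/ordered vector of length n with ordinal
#'   severity hints used only to orient the PC1 sign.
#' @return a [SeverityModel-class].
#' @examples
#' X <- matrix(rnorm(60), 10, 6)
#' m <- fitSeverityModel(X)
#' varianceFraction(m, 1)
#' @export
fitSeverityModel <- function(X, center = TRUE, standardize = FALSE,
                             labels = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("at least two training cutouts are required")
  if (anyNA(X) || !all(is.finite(X))) stop("feature matrix must be finite")
  n <- nrow(X); m <- ncol(X)
  ctr <- if (center) colMeans(X) else rep(0, m)
  scl <- if (standardize) apply(X, 2, stats::sd) else rep(1, m)
  if (any(scl == 0)) stop("zero-variance feature: cannot standardise")
  Xc <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  S <- crossprod(Xc) / (n * m)
  if (max(abs(S)) == 0) stop("degenerate fit: feature matrix has no variation")
  eig <- eigen(S, symmetric = TRUE)
  evec <- eig$vectors
  eval <- pmax(eig$values, 0)
  pc1 <- drop(Xc %*% evec[, 1])
  sgn <- 1
  if (!is.null(labels)) {
    r <- suppressWarnings(stats::cor(pc1, as.numeric(labels)))
    if (is.finite(r) && r < 0) sgn <- -1
  } else {
    if (evec[which.max(abs(evec[, 1])), 1] < 0) sgn <- -1
  }
  rng <- range(sgn * pc1)
  if (!(rng[2] > rng[1]))
    stop("degenerate fit: training PC1 projections are constant")
  fn <- colnames(X)
  if (is.null(fn)) fn <- sprintf("feature_%03d", seq_len(m))
  new("SeverityModel",
      eigenvectors = evec, eigenvalues = eval,
      center = ctr, scale = scl, sign = sgn, pc1Range = rng,
      featureNames = fn, centering = center, standardize = standardize)
}

#' Fraction of total variation carried by a principal component
#'
#' \eqn{\lambda_k / \sum_j \lambda_j}; the per-component heights of the
#' scree plot.  For the source protocol's data PC1 carried 97\% (mice) and
#' 71\% (human) of the total variation.
#'
#' @param model a [SeverityModel-class].
#' @param k component index or vector of indices (1-based).
#' @return numeric vector of fractions in [0, 1].
#' @export
varianceFraction <- function(model, k = 1L) {
  stopifnot(is(model, "SeverityModel"))
  ev <- model@eigenvalues
  if (any(k < 1L) || any(k > length(ev)))
    stop("component index out of range")
  ev[k] / sum(ev)
}

#' Scree table of a severity model
#'
#' @param model a [SeverityModel-class].
#' @param nComponents how many leading components to report (default 10).
#' @return data.frame with \code{component}, \code{eigenvalue},
#'   \code{variance_fraction}.
#' @export
screeTable <- function(model, nComponents = 10L) {
  stopifnot(is(model, "SeverityModel"))
  k <- seq_len(min(nComponents, length(model@eigenvalues)))
  data.frame(component = k,
             eigenvalue = model@eigenvalues[k],
             variance_fraction = varianceFraction(model, k))
}

#' Severity scores of feature vectors under a fitted model
#'
#' Projects each feature vector onto the oriented first eigenvector (after
#' the model's centring/scaling) and min-max normalises against the
#' training-set PC1 range: a score of 1 marks the most severe inflammation
#' seen in training, 0 no inflammation.  Projections outside the training
#' range are clipped to [0, 1] and flagged, since the scale is defined only
#' on the training cohort.
#'
#' @param model a [SeverityModel-class].
#' @param features a single feature vector or a cutouts x features matrix
#'   whose columns match the model's features.
#' @return data.frame with \code{cutout_id}, \code{raw_pc1}, \code{score},
#'   \code{clipped}.
#' @export
severityScore <- function(model, features) {
  stopifnot(is(model, "SeverityModel"))
  X <- if (is.matrix(features)) features else
    matrix(features, nrow = 1, dimnames = list(NULL, names(features)))
  m <- length(model@featureNames)
  if (ncol(X) != m)
    stop(sprintf("feature length %d does not match model (%d)", ncol(X), m))
  if (!is.null(colnames(X)) && !identical(colnames(X), model@featureNames))
    stop("feature names do not match the model's bank layout")
  Xc <- sweep(sweep(X, 2, model@center, "-"), 2, model@scale, "/")
  raw <- model@sign * drop(Xc %*% model@eigenvectors[, 1])
  rng <- model@pc1Range
  sc <- (raw - rng[1]) / (rng[2] - rng[1])
  # tolerance so training endpoints are not flagged after serialisation
  clipped <- sc < -1e-9 | sc > 1 + 1e-9
  sc <- pmin(pmax(sc, 0), 1)
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("cutout_%03d", seq_len(nrow(X)))
  data.frame(cutout_id = ids, raw_pc1 = raw, score = sc, clipped = clipped,
             row.names = NULL)
}

#' Per-feature contributions to the severity axis
#'
#' The entries of the oriented first eigenvector, keyed by feature name and
#' annotated with the bank coordinates each feature came from.  Large
#' absolute weights identify which filter triples and which statistic
#' (mean, skewness, entropy) drive the score.
#'
#' @param model a [SeverityModel-class].
#' @return data.frame with \code{feature}, \code{bandwidth}, \code{lambda},
#'   \code{gamma}, \code{stat}, \code{weight}, in bank order.
#' @export
contributions <- function(model) {
  stopifnot(is(model, "SeverityModel"))
  w <- model@sign * model@eigenvectors[, 1]
  fn <- model@featureNames
  parts <- regmatches(fn, regexec(
    "^b([0-9.]+)_lam([0-9.]+)_gam([0-9.]+)_(mean|skew|entropy)$", fn))
  ok <- lengths(parts) == 5L
  num <- function(i) ifelse(ok, as.numeric(vapply(
    parts, function(p) if (length(p) == 5L) p[i] else NA_character_,
    character(1))), NA_real_)
  data.frame(feature = fn,
             bandwidth = num(2), lambda = num(3), gamma = num(4),
             stat = ifelse(ok, vapply(parts, function(p)
               if (length(p) == 5L) p[5] else NA_character_, character(1)),
               NA_character_),
             weight = w, row.names = NULL)
}

#' Grouped summary of severity-axis contributions
#'
#' Sums of squared PC1 loadings by statistic or by filter triple (the
#' loadings have unit total, so each group's share is directly
#' interpretable as a fraction of the axis).
#'
#' @param model a [SeverityModel-class].
#' @param by \code{"stat"} (mean/skew/entropy) or \code{"map"} (one row per
#'   \eqn{(b, \lambda, \gamma)} triple).
#' @return data.frame with the grouping columns and \code{weight_sq}.
#' @export
contributionSummary <- function(model, by = c("stat", "map")) {
  by <- match.arg(by)
  co <- contributions(model)
  co$weight_sq <- co$weight^2
  if (by == "stat") {
    out <- stats::aggregate(weight_sq ~ stat, co, sum)
  } else {
    out <- stats::aggregate(weight_sq ~ bandwidth + lambda + gamma, co, sum)
  }
  out[order(-out$weight_sq), , drop = FALSE]
}

#' Serialise / restore a severity model as JSON
#'
#' Stores eigenvectors, eigenvalues, centring, scaling, sign, PC1 range,
#' feature names and configuration flags; plain-text and
#' cross-version-stable.
#'
#' @param model a [SeverityModel-class].
#' @param path JSON file path.
#' @return \code{readSeverityModel} returns the restored model.
#' @export
writeSeverityModel <- function(model, path) {
  stopifnot(is(model, "SeverityModel"))
  obj <- list(format = "gaborSeverity/model/v1",
              eigenvectors = model@eigenvectors,
              eigenvalues = model@eigenvalues,
              center = model@center, scale = model@scale,
              sign = model@sign, pc1_range = model@pc1Range,
              feature_names = model@featureNames,
              centering = model@centering, standardize = model@standardize)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeSeverityModel
#' @export
readSeverityModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "gaborSeverity/model/v1"))
    stop("not a gaborSeverity model file")
  new("SeverityModel",
      eigenvectors = as.matrix(obj$eigenvectors),
      eigenvalues = as.numeric(obj$eigenvalues),
      center = as.numeric(obj$center), scale = as.numeric(obj$scale),
      sign = as.numeric(obj$sign), pc1Range = as.numeric(obj$pc1_range),
      featureNames = as.character(obj$feature_names),
      centering = as.logical(obj$centering),
      standardize = as.logical(obj$standardize))
}
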