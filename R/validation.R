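## Pairwise double-blind validation of the severity score: an expert is
## shown two cutouts and picks the more severely inflamed one; agreement is
## the fraction of non-tied pairs where the expert picked the
## higher-scoring cutout.  The mismatch ratio as a function of the score
## difference defines the method's effective resolution.

# Run expr with a private RNG state seeded by `seed`; the caller's
# .Random.seed is untouched.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sample random cutout pairs for expert comparison
#'
#' Each pair is drawn uniformly among unordered pairs of distinct ids;
#' pairs are drawn independently (with replacement across pairs), mirroring
#' the random two-image presentation of the comparison software.
#'
#' @param ids character or numeric vector of at least 2 cutout identifiers.
#' @param nPairs number of pairs to draw.
#' @param seed integer seed; the global RNG state is left untouched.
#' @return data.frame with columns \code{id_a}, \code{id_b}.
#' @export
samplePairs <- function(ids, nPairs, seed = 1L) {
  if (length(ids) < 2) stop("at least two ids are required")
  stopifnot(nPairs >= 1)
  .withSeed(seed, {
    ab <- replicate(nPairs, sample(length(ids), 2L, replace = FALSE))
  })
  data.frame(id_a = ids[ab[1, ]], id_b = ids[ab[2, ]],
             stringsAsFactors = FALSE)
}

#' Assemble pairwise comparison records
#'
#' Joins expert choices with severity scores: for every pair, the score
#' difference \code{delta = |score_a - score_b|} and whether the expert
#' picked the higher-scoring cutout (\code{agree}).  Pairs with exactly
#' equal scores are marked as ties (\code{agree = NA}); ties can occur
#' after clipping and are excluded from rates.
#'
#' @param pairs data.frame with \code{id_a}, \code{id_b} and
#'   \code{expert_choice} (values \code{"a"} or \code{"b"}); e.g. an expert
#'   choices CSV read with \code{read.csv}.
#' @param scores named numeric vector of severity scores in [0, 1], or the
#'   data.frame returned by [severityScore()].
#' @return data.frame with \code{id_a}, \code{id_b}, \code{score_a},
#'   \code{score_b}, \code{expert_choice}, \code{delta}, \code{agree}.
#' @export
comparisonRecords <- function(pairs, scores) {
  if (is.data.frame(scores)) {
    s <- stats::setNames(scores$score, scores$cutout_id)
  } else s <- scores
  need <- c("id_a", "id_b", "expert_choice")
  if (!all(need %in% names(pairs)))
    stop("pairs must have columns id_a, id_b, expert_choice")
  if (!all(pairs$expert_choice %in% c("a", "b")))
    stop("expert_choice must be 'a' or 'b'")
  miss <- setdiff(unique(c(pairs$id_a, pairs$id_b)), names(s))
  if (length(miss))
    stop("no score for id(s): ", paste(utils::head(miss, 5), collapse = ", "))
  sa <- unname(s[pairs$id_a]); sb <- unname(s[pairs$id_b])
  higher <- ifelse(sa > sb, "a", ifelse(sb > sa, "b", NA))
  data.frame(id_a = pairs$id_a, id_b = pairs$id_b,
             score_a = sa, score_b = sb,
             expert_choice = pairs$expert_choice,
             delta = abs(sa - sb),
             agree = pairs$expert_choice == higher,
             stringsAsFactors = FALSE)
}

#' Overall expert-agreement rate
#'
#' Fraction of non-tied comparison records where the expert's choice
#' matched the score ordering.
#'
#' @param records data.frame from [comparisonRecords()].
#' @return the rate (scalar in [0, 1]) with attributes \code{n_ties} and
#'   \code{n_used}.
#' @export
agreementRate <- function(records) {
  ok <- !is.na(records$agree)
  if (!any(ok)) stop("agreement rate undefined: all records are ties")
  structure(mean(records$agree[ok]),
            n_ties = sum(!ok), n_used = sum(ok))
}

#' Mismatch ratio as a function of score difference
#'
#' Bins the comparison records by \code{delta} into equal-width bins over
#' [0, 1] and reports the per-bin mismatch ratio (1 - agreement among
#' non-tied records).  The decay of this curve with growing delta shows how
#' large a score difference must be before expert opinion reliably agrees
#' with the score ordering.
#'
#' @param records data.frame from [comparisonRecords()].
#' @param nBins number of bins (default 20).
#' @return data.frame with \code{bin_lo}, \code{bin_hi}, \code{mismatch}
#'   (NA for empty bins), \code{count}, \code{empty}.
#' @export
mismatchCurve <- function(records, nBins = 20L) {
  stopifnot(nrow(records) >= 1, nBins >= 2L)
  breaks <- seq(0, 1, length.out = nBins + 1L)
  ok <- !is.na(records$agree)
  idx <- .bincode(pmin(records$delta[ok], 1), breaks, include.lowest = TRUE)
  count <- tabulate(idx, nbins = nBins)
  mis <- rep(NA_real_, nBins)
  if (any(ok)) {
    disagree <- tapply(!records$agree[ok], factor(idx, levels = seq_len(nBins)),
                       sum)
    mis[count > 0] <- as.numeric(disagree[count > 0]) / count[count > 0]
  }
  data.frame(bin_lo = breaks[-(nBins + 1L)], bin_hi = breaks[-1L],
             mismatch = mis, count = count, empty = count == 0L)
}

#' Effective resolution of the score from the mismatch curve
#'
#' The smallest score difference beyond which expert mismatch stays at or
#' below an acceptable threshold: the lower edge of the first bin from
#' which every later non-empty bin has mismatch <= \code{threshold}.
#' Returns \code{NA} when no such point exists.  Empty bins carry no
#' evidence and are skipped.  A warning is raised when the curve is not
#' monotone decreasing in trend.
#'
#' @param curve data.frame from [mismatchCurve()].
#' @param threshold highest acceptable mismatch ratio.
#' @return a delta value (bin edge), or \code{NA}.
#' @export
resolutionEstimate <- function(curve, threshold) {
  mis <- curve$mismatch
  filled <- which(!is.na(mis))
  if (!length(filled)) return(NA_real_)
  trend <- if (length(filled) > 1)
    suppressWarnings(stats::cor(seq_along(filled), mis[filled],
                                method = "spearman")) else NA
  if (isTRUE(trend > 0))
    warning("mismatch curve has an increasing trend; resolution estimate ",
            "may be unreliable")
  okFrom <- vapply(seq_len(nrow(curve)), function(j) {
    later <- filled[filled >= j]
    all(mis[later] <= threshold)
  }, logical(1))
  if (!any(okFrom)) return(NA_real_)
  curve$bin_lo[which(okFrom)[1]]
}

#' Simulate expert choices over scored pairs
#'
#' Stand-in for human raters in tests and calibration experiments.  A
#' \code{"perfect"} expert always picks the higher-scoring cutout; a
#' \code{"logistic"} expert errs with probability
#' \eqn{P(mistake) = 1 / (1 + e^{k \delta})}, i.e. coin-flipping at
#' \eqn{\delta = 0} and increasingly reliable as the score difference
#' grows.  Tied pairs are decided by a fair coin.
#'
#' @param pairs data.frame with \code{id_a}, \code{id_b}.
#' @param scores named numeric vector or [severityScore()] data.frame.
#' @param model \code{"perfect"} or \code{"logistic"}.
#' @param k steepness of the logistic error decay (default 10).
#' @param seed integer seed (global RNG untouched).
#' @return the \code{pairs} data.frame with an \code{expert_choice} column.
#' @export
simulateExpert <- function(pairs, scores, model = c("perfect", "logistic"),
                           k = 10, seed = 1L) {
  model <- match.arg(model)
  if (is.data.frame(scores)) scores <- stats::setNames(scores$score,
                                                       scores$cutout_id)
  sa <- unname(scores[pairs$id_a]); sb <- unname(scores[pairs$id_b])
  higher <- ifelse(sa >= sb, "a", "b")
  lower <- ifelse(higher == "a", "b", "a")
  n <- nrow(pairs)
  choice <- .withSeed(seed, {
    tieFlip <- sample(c("a", "b"), n, replace = TRUE)
    if (model == "perfect") {
      mistake <- rep(FALSE, n)
    } else {
      pm <- 1 / (1 + exp(k * abs(sa - sb)))
      mistake <- stats::runif(n) < pm
    }
    out <- ifelse(mistake, lower, higher)
    ifelse(sa == sb, tieFlip, out)
  })
  pairs$expert_choice <- choice
  pairs
}
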