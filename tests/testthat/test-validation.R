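test_that("samplePairs draws distinct ids reproducibly", {
  p <- samplePairs(c("x", "y"), 10, seed = 3)
  expect_identical(nrow(p), 10L)
  expect_true(all(sort(c(p$id_a[1], p$id_b[1])) == c("x", "y")))
  expect_true(all(p$id_a != p$id_b))
  # determinism contract
  expect_identical(samplePairs(letters, 50, seed = 9),
                   samplePairs(letters, 50, seed = 9))
  expect_false(identical(samplePairs(letters, 50, seed = 9),
                         samplePairs(letters, 50, seed = 10)))
  # the study-scale design: 150 ids, 3402 pairs
  ids <- sprintf("c%03d", 1:150)
  big <- samplePairs(ids, 3402, seed = 1)
  expect_identical(nrow(big), 3402L)
  expect_true(all(big$id_a != big$id_b))
  expect_error(samplePairs("only", 5), "two ids")
  # the caller's RNG stream is untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(samplePairs(letters, 5, seed = 77))
  expect_identical(runif(1), before)
})

test_that("comparison records join scores with expert choices", {
  scores <- c(a1 = 0.1, a2 = 0.6, a3 = 0.6, a4 = 0.9)
  pairs <- data.frame(id_a = c("a1", "a2", "a2", "a4"),
                      id_b = c("a2", "a1", "a3", "a1"),
                      expert_choice = c("b", "a", "a", "a"))
  rec <- comparisonRecords(pairs, scores)
  expect_equal(rec$delta, c(0.5, 0.5, 0, 0.8))
  expect_identical(rec$agree, c(TRUE, TRUE, NA, TRUE))
  expect_error(comparisonRecords(
    data.frame(id_a = "a1", id_b = "zz", expert_choice = "a"), scores),
    "no score")
  expect_error(comparisonRecords(
    data.frame(id_a = "a1", id_b = "a2", expert_choice = "left"), scores),
    "expert_choice")
})

test_that("agreementRate counts non-tied records and reports ties", {
  scores <- c(a = 0.2, b = 0.4, c = 0.9)
  pairs <- samplePairs(names(scores), 200, seed = 5)
  perfect <- simulateExpert(pairs, scores, model = "perfect")
  rec <- comparisonRecords(perfect, scores)
  r <- agreementRate(rec)
  expect_equal(as.numeric(r), 1)
  expect_identical(attr(r, "n_ties"), 0L)
  # hand-built 4 records, 3 agreeing
  rec4 <- data.frame(agree = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(as.numeric(agreementRate(rec4)), 0.75)
  # an expert choosing at random agrees about half the time
  set.seed(13)
  n <- 4000
  prand <- samplePairs(sprintf("c%02d", 1:50), n, seed = 15)
  sc50 <- setNames(seq(0, 1, length.out = 50), sprintf("c%02d", 1:50))
  prand$expert_choice <- sample(c("a", "b"), n, replace = TRUE)
  rrand <- as.numeric(agreementRate(comparisonRecords(prand, sc50)))
  expect_lt(abs(rrand - 0.5), 3 * sqrt(0.25 / n))
  # all ties: undefined
  tied <- data.frame(agree = c(NA, NA))
  expect_error(agreementRate(tied), "ties")
})

test_that("mismatchCurve bins by score difference and flags empty bins", {
  ids <- sprintf("c%03d", 1:101)
  scores <- setNames(seq(0, 1, length.out = 101), ids)
  pairs <- samplePairs(ids, 3000, seed = 19)
  perfect <- comparisonRecords(simulateExpert(pairs, scores), scores)
  cv <- mismatchCurve(perfect, nBins = 20)
  expect_identical(nrow(cv), 20L)
  expect_true(all(cv$mismatch[!cv$empty] == 0))
  # a step expert: wrong iff delta <= 0.3
  rec <- perfect
  rec$agree <- rec$delta > 0.3
  cvs <- mismatchCurve(rec, nBins = 20)
  lowBins <- !cvs$empty & cvs$bin_hi <= 0.3
  highBins <- !cvs$empty & cvs$bin_lo >= 0.3
  expect_true(all(cvs$mismatch[lowBins] == 1))
  expect_true(all(cvs$mismatch[highBins] == 0))
  # weighted bin average reproduces 1 - overall agreement exactly
  ok <- !is.na(rec$agree)
  overall <- as.numeric(agreementRate(rec))
  wavg <- sum(cvs$mismatch[!cvs$empty] * cvs$count[!cvs$empty]) / sum(cvs$count)
  expect_equal(wavg, 1 - overall, tolerance = 1e-12)
})

test_that("logistic-error experts follow the expected mismatch curve", {
  ids <- sprintf("c%03d", 1:150)
  scores <- setNames(seq(0, 1, length.out = 150), ids)
  k <- 10
  pairs <- samplePairs(ids, 2000, seed = 23)
  sim <- simulateExpert(pairs, scores, model = "logistic", k = k, seed = 29)
  rec <- comparisonRecords(sim, scores)
  cv <- mismatchCurve(rec, nBins = 10)
  ok <- !is.na(rec$agree)
  binIdx <- .bincode(rec$delta, seq(0, 1, length.out = 11),
                     include.lowest = TRUE)
  for (b in which(!cv$empty)) {
    inBin <- ok & binIdx == b
    pExp <- 1 / (1 + exp(k * rec$delta[inBin]))
    mu <- mean(pExp)
    se <- sqrt(sum(pExp * (1 - pExp))) / sum(inBin)
    expect_lt(abs(cv$mismatch[b] - mu), 3 * se + 1e-9)
  }
})

test_that("resolutionEstimate reads the acceptable-mismatch point", {
  ids <- sprintf("c%03d", 1:101)
  scores <- setNames(seq(0, 1, length.out = 101), ids)
  pairs <- samplePairs(ids, 3000, seed = 31)
  rec <- comparisonRecords(simulateExpert(pairs, scores), scores)
  cv <- mismatchCurve(rec, nBins = 20)
  expect_equal(resolutionEstimate(cv, 0.05), 0)  # perfect expert
  # step expert: mismatch 1 below delta = 0.3
  recS <- rec
  recS$agree <- recS$delta > 0.3
  cvS <- mismatchCurve(recS, nBins = 20)
  res <- suppressWarnings(resolutionEstimate(cvS, 0.05))
  expect_lt(abs(res - 0.3), 0.05 + 1e-12)
  # random expert: no resolution at strict thresholds
  recR <- rec
  set.seed(37)
  recR$agree <- sample(c(TRUE, FALSE), nrow(recR), replace = TRUE)
  expect_true(is.na(suppressWarnings(resolutionEstimate(
    mismatchCurve(recR, nBins = 20), 0.05))))
})

test_that("agreement statistics are exchangeable over record order", {
  ids <- sprintf("c%03d", 1:40)
  scores <- setNames(runif(40), ids)
  pairs <- samplePairs(ids, 500, seed = 41)
  rec <- comparisonRecords(
    simulateExpert(pairs, scores, model = "logistic", k = 5, seed = 43),
    scores)
  set.seed(47)
  shuf <- rec[sample(nrow(rec)), ]
  expect_equal(as.numeric(agreementRate(shuf)),
               as.numeric(agreementRate(rec)))
  expect_equal(mismatchCurve(shuf, 15)$mismatch, mismatchCurve(rec, 15)$mismatch)
})
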