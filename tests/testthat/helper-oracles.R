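# Independent reference implementations used as oracles, plus small shared
# fixtures.  All oracles are deliberately naive (loops, dense algebra) and
# share no code with the package internals they check.

# True convolution with symmetric-reflection padding, by explicit shifts.
directConvolveReflect <- function(img, k) {
  h <- (nrow(k) - 1) / 2
  nr <- nrow(img); nc <- ncol(img)
  ri <- c(h:1, 1:nr, nr:(nr - h + 1))
  ci <- c(h:1, 1:nc, nc:(nc - h + 1))
  P <- img[ri, ci]
  out <- matrix(0, nr, nc)
  for (dy in -h:h) for (dx in -h:h)
    out <- out + k[dy + h + 1, dx + h + 1] *
      P[(1:nr) + h - dy, (1:nc) + h - dx]
  out
}

# Two-loop mean / skewness; loop-built histogram entropy.
loopMean <- function(m) {
  s <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) s <- s + m[i, j]
  s / (nrow(m) * ncol(m))
}

loopSkewness <- function(m) {
  mu <- loopMean(m)
  s2 <- 0; s3 <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    d <- m[i, j] - mu
    s2 <- s2 + d^2
    s3 <- s3 + d^3
  }
  n <- nrow(m) * ncol(m)
  (s3 / n) / (s2 / n)^1.5
}

loopEntropy <- function(m, bins = 256L) {
  v <- as.vector(m)
  lo <- min(v); hi <- max(v)
  if (lo == hi) return(0)
  counts <- integer(bins)
  for (x in v) {
    b <- floor((x - lo) / (hi - lo) * bins) + 1L
    if (b > bins) b <- bins
    counts[b] <- counts[b] + 1L
  }
  p <- counts[counts > 0] / length(v)
  -sum(p * log2(p))
}

# A small bank (2 orientations, single triple) reused across tests.
miniBank <- function() {
  buildGaborBank(theta = c(0, 90), gamma = 0.5, lambda = 20, bandwidth = 5)
}

# Fake per-filter response lists for pooling tests, built from a bank's
# layout without any convolution.
fakeResponses <- function(bank, fill) {
  lapply(seq_len(nKernels(bank)), fill)
}
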