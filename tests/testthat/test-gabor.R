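test_that("bandwidth/sigma-ratio conversions match hand-evaluated values", {
  # frozen values of (1/pi) * (sqrt(ln 2)/2) * (2^b + 1)/(2^b - 1)
  expect_equal(bandwidthToSigmaRatio(5), 0.141053903164, tolerance = 1e-9)
  expect_equal(bandwidthToSigmaRatio(10), 0.132764233923, tolerance = 1e-9)
  expect_equal(bandwidthToSigmaRatio(15), 0.132513269481, tolerance = 1e-9)
  expect_equal(bandwidthToSigmaRatio(20), 0.132505434494, tolerance = 1e-9)
  expect_equal(bandwidthToSigmaRatio(1), 0.397515545279, tolerance = 1e-9)
  expect_error(bandwidthToSigmaRatio(0), "positive")
  expect_error(bandwidthToSigmaRatio(-2), "positive")
})

test_that("the bandwidth conversion round-trips exactly", {
  for (b in seq(0.5, 20, by = 0.5))
    expect_lt(abs(sigmaRatioToBandwidth(bandwidthToSigmaRatio(b)) - b), 1e-9)
  # beyond ~20 octaves the ratio sits within ~2^-b of its pole, so the
  # inversion loses roughly b bits: only a looser bound is meaningful
  for (b in seq(20.5, 25, by = 0.5))
    expect_lt(abs(sigmaRatioToBandwidth(bandwidthToSigmaRatio(b)) - b), 1e-7)
  # pole: ratios at or below the large-b limit have no finite bandwidth
  expect_error(sigmaRatioToBandwidth(0.1325), "exceed")
  expect_error(sigmaRatioToBandwidth(sqrt(log(2)) / 2 / pi), "exceed")
})

test_that("gaborKernel samples the Gabor function correctly", {
  k <- gaborKernel(lambda = 20, theta = 0, gamma = 0.5, bandwidth = 5)
  side <- nrow(k)
  expect_identical(side %% 2L, 1L)
  c0 <- (side + 1L) %/% 2L
  expect_equal(k[c0, c0], 1)  # cos(0) * exp(0) at the origin
  # support covers 3 sd of the widest envelope axis (gamma < 1 widens y')
  p <- attr(k, "params")
  expect_gte(side, 2 * ceiling(3 * p$sigma / 0.5) + 1)
  # hand-evaluated value at (x, y) = (10, 0): exp(-100/(2 sigma^2)) cos(pi)
  expect_equal(k[c0, c0 + 10], -0.0018685256288, tolerance = 1e-8)
  # phase-0 kernels are even under point reflection, for any orientation
  for (th in c(0, 30, 75)) {
    kt <- gaborKernel(lambda = 25, theta = th, gamma = 2, bandwidth = 10)
    expect_equal(kt, kt[rev(seq_len(nrow(kt))), rev(seq_len(ncol(kt)))],
                 ignore_attr = TRUE)
  }
  # theta and theta + 180 give identical kernels (cosine carrier, phase 0)
  k0 <- gaborKernel(30, 40, 2, 5)
  k180 <- gaborKernel(30, 220, 2, 5)
  expect_equal(k0, k180, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("buildGaborBank takes the Cartesian product in canonical order", {
  bank <- buildGaborBank()
  expect_identical(nKernels(bank), 216L)
  expect_s4_class(bank, "GaborBank")
  p <- bankParams(bank)
  # orientation innermost: first six rows share (b, lambda, gamma)
  expect_identical(p$theta[1:6], c(0, 30, 60, 90, 120, 150))
  expect_identical(length(unique(p$bandwidth[1:54])), 1L)  # b slowest
  expect_identical(nKernels(buildGaborBank(theta = 0, gamma = 1,
                                           lambda = 20, bandwidth = 5)), 1L)
  expect_identical(nKernels(buildGaborBank(theta = c(0, 90), gamma = 1,
                                           lambda = 20, bandwidth = 5)), 2L)
  expect_error(buildGaborBank(theta = numeric(0)), "nonempty")
  # bank size is always the product of the grid sizes
  b2 <- buildGaborBank(theta = c(0, 45, 90), gamma = c(1, 2),
                       lambda = c(15, 25), bandwidth = c(2, 5))
  expect_identical(nKernels(b2), 3L * 2L * 2L * 2L)
})

test_that("FFT convolution matches the direct oracle and convolves truly", {
  set.seed(17)
  img <- matrix(runif(64 * 64), 64)
  for (side in c(5L, 11L, 21L)) {
    k <- matrix(rnorm(side^2), side)  # asymmetric: pins the flip convention
    expect_lt(max(abs(convolveReflect(img, k) -
                        directConvolveReflect(img, k))), 1e-8)
  }
  # convolving an impulse reproduces the kernel (the convolution identity)
  k <- matrix(rnorm(9 * 9), 9)
  imp <- matrix(0, 64, 64); imp[33, 33] <- 1
  r <- convolveReflect(imp, k)
  expect_lt(max(abs(r[33 + (-4:4), 33 + (-4:4)] - k)), 1e-10)
})

test_that("applyBank responds as convolution theory predicts", {
  bank <- miniBank()
  flat <- matrix(0.6, 512, 512)
  resp <- applyBank(flat, bank)
  expect_length(resp, 2L)
  # constant image: response is pixel value times the kernel weight sum
  for (i in 1:2) {
    ws <- sum(gaborKernels(bank)[[i]])
    expect_lt(max(abs(resp[[i]] - 0.6 * ws)), 1e-10 * (1 + abs(ws)))
  }
  expect_error(applyBank(matrix(0, 100, 100), bank), "512")
  # linearity in the image
  set.seed(4)
  img <- matrix(runif(512 * 512), 512)
  r1 <- applyBank(img, bank)[[1]]
  r3 <- applyBank(3 * img, bank)[[1]]
  expect_lt(max(abs(r3 - 3 * r1)), 1e-8 * max(abs(r1)))
})

test_that("narrowband filters select their matching grating wavelength", {
  # wavelength selectivity is a narrowband property; at the default protocol
  # bandwidths (5-20 octaves) the filters are nearly lowpass, so probe with
  # a 1-octave kernel
  k <- gaborKernel(lambda = 30, theta = 0, gamma = 2, bandwidth = 1)
  amps <- vapply(c(10, 15, 20, 30, 45, 60), function(l0) {
    # carrier varies along x (columns), matching theta = 0
    g <- outer(seq_len(128), seq_len(128),
               function(y, x) cos(2 * pi * x / l0))
    r <- convolveReflect(g, k)
    ctr <- r[33:96, 33:96]
    max(ctr) - min(ctr)
  }, numeric(1))
  expect_identical(which.max(amps), 4L)  # lambda0 = 30
})

test_that("orientation pooling takes the signed elementwise maximum", {
  bank <- miniBank()  # 2 orientations, one triple
  m1 <- matrix(c(1, -5, 3, 0), 2)
  m2 <- matrix(c(0, 2, -1, 4), 2)
  st <- orientationMax(list(m1, m2), bank)
  expect_s4_class(st, "ResponseStack")
  expect_length(responseMaps(st), 1L)
  expect_equal(responseMaps(st)[[1]], pmax(m1, m2))
  # identical maps pool to themselves
  st2 <- orientationMax(list(m1, m1), bank)
  expect_equal(responseMaps(st2)[[1]], m1)
  # a dominant orientation wins everywhere
  st3 <- orientationMax(list(m1, m1 - 10), bank)
  expect_equal(responseMaps(st3)[[1]], m1)
  # magnitude pooling is available
  st4 <- orientationMax(list(m1, m2), bank, pool = "magnitude")
  expect_equal(responseMaps(st4)[[1]], pmax(abs(m1), abs(m2)))
  expect_error(orientationMax(list(m1), bank), "expected 2")
})

test_that("the default bank pools to 36 maps with consistent indexing", {
  bank <- buildGaborBank()
  resp <- fakeResponses(bank, function(i) matrix(i, 2, 2))
  st <- orientationMax(resp, bank)
  expect_length(responseMaps(st), 36L)
  idx <- mapIndex(st)
  expect_identical(nrow(idx), 36L)
  # within each group of 6 orientations the max index is the 6th filter
  expect_equal(responseMaps(st)[[1]][1, 1], 6)
  expect_equal(responseMaps(st)[[36]][1, 1], 216)
  # index follows bank ordering: bandwidth slowest
  expect_identical(idx$bandwidth, rep(c(5, 10, 15, 20), each = 9))
  expect_identical(idx$gamma[1:3], c(0.5, 2, 4))
})

test_that("pooled responses tolerate texture rotation by the grid step", {
  # oriented stripe texture rotated by multiples of the bank's 30-degree
  # orientation spacing: pooled map means should be nearly unchanged
  bank <- buildGaborBank(theta = c(0, 30, 60, 90, 120, 150), gamma = 2,
                         lambda = 30, bandwidth = 5)
  idx <- seq(0, 255)
  means <- vapply(c(10, 40, 70, 100, 130, 160), function(a) {
    th <- a * pi / 180
    tex <- outer(idx, idx, function(y, x)
      0.75 + 0.2 * (cos(2 * pi * (x * cos(th) + y * sin(th)) / 30) > 0))
    st <- responseStack(tex, bank, size = 256L)
    mean(responseMaps(st)[[1]])
  }, numeric(1))
  expect_lt((max(means) - min(means)) / abs(mean(means)), 0.05)
})

test_that("responseStack streams cutouts with identical results", {
  bank <- miniBank()
  set.seed(8)
  cu <- matrix(runif(512 * 512), 512)
  viaApply <- orientationMax(applyBank(cu, bank), bank)
  viaStack <- responseStack(cu, bank)
  expect_equal(responseMaps(viaStack), responseMaps(viaApply))
  # list input returns one stack per cutout, ids from names
  st <- responseStack(list(a = cu, b = cu / 2), bank)
  expect_length(st, 2L)
  expect_identical(st[[2]]@cutoutId, "b")
})

test_that("bank serialisation round-trips through JSON", {
  bank <- buildGaborBank(theta = c(0, 60, 120), gamma = c(0.5, 4),
                         lambda = 25, bandwidth = c(5, 20))
  path <- withr::local_tempfile(fileext = ".json")
  writeGaborBank(bank, path)
  back <- readGaborBank(path)
  expect_equal(bankParams(back), bankParams(bank))
  expect_equal(gaborKernels(back), gaborKernels(bank))
})
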