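test_that("hard and soft rules match their closed forms", {
  expect_equal(hardThreshold(5, 3), 5)
  expect_equal(hardThreshold(2, 3), 0)
  expect_equal(hardThreshold(-5, 3), -5)
  expect_equal(softThreshold(5, 3), 2)
  expect_equal(softThreshold(-5, 3), -2)
  expect_equal(softThreshold(2, 3), 0)
  a <- c(-4.2, -0.3, 0, 1.7, 9)
  expect_equal(hardThreshold(a, 0), a)   # zero threshold is the identity
  expect_equal(softThreshold(a, 0), a)
  expect_error(hardThreshold(1, -1), "nonnegative")
  expect_error(softThreshold(1, -1), "nonnegative")
})

test_that("soft is a contraction, hard preserves signs, zero-sets grow with S", {
  set.seed(21)
  a <- rnorm(500, sd = 2)
  prevHard <- prevSoft <- rep(FALSE, length(a))
  for (s in c(0, 0.5, 1, 2, 4)) {
    hs <- hardThreshold(a, s)
    ss <- softThreshold(a, s)
    expect_true(all(abs(ss) <= abs(a)))
    expect_true(all(hs == 0 | sign(hs) == sign(a)))
    expect_true(all(abs(ss) <= abs(hs)))
    # monotonicity: once zeroed, stays zeroed at larger S
    expect_true(all(!prevHard | hs == 0))
    expect_true(all(!prevSoft | ss == 0))
    prevHard <- hs == 0
    prevSoft <- ss == 0
    # idempotence of the hard rule
    expect_equal(hardThreshold(hs, s), hs)
  }
})

test_that("universal threshold follows sigma * sqrt(2 log M)", {
  expect_equal(visuShrinkThreshold(123.4, 1), 0)
  expect_equal(visuShrinkThreshold(0, 4096), 0)
  expect_equal(visuShrinkThreshold(2, 65536), 9.4192802, tolerance = 1e-7)
  expect_error(visuShrinkThreshold(-1, 10), "nonnegative")
  expect_error(visuShrinkThreshold(1, 0), ">= 1")
})

test_that("threshold policy enforces the VisuShrink identity", {
  p <- thresholdPolicy("soft", sigma = 0.1, m = 16384)
  expect_equal(p@threshold, 0.1 * sqrt(2 * log(16384)), tolerance = 1e-13)
  expect_error(thresholdPolicy("soft"), "sigma")
  # a stated threshold inconsistent with its sigma/m is rejected
  expect_error(new("ThresholdPolicy", mode = "soft", threshold = 1,
                   sigma = 0.1, m = 16384, sigmaSource = "given"),
               "sigma")
})

test_that("MAD noise estimator recovers sigma and vanishes without noise", {
  # noise-free: constant image has all-zero details
  s <- dwt2(matrix(0.4, 32, 32), "haar")
  expect_equal(estimateNoiseSigma(s), 0)
  # consistency on pure Gaussian noise fields
  for (seed in 1:20) {
    set.seed(seed)
    x <- matrix(rnorm(256 * 256, sd = 0.1), 256, 256)
    est <- estimateNoiseSigma(dwt2(x, "haar"))
    expect_gt(est, 0.09)
    expect_lt(est, 0.11)
  }
})

test_that("thresholding touches details only and respects S extremes", {
  x <- randomImage(16, 16, 8)
  s <- dwt2(x, "haar", levels = 2)

  s0 <- applyThreshold(s, thresholdPolicy("soft", threshold = 0))
  expect_equal(s0@details, s@details)

  big <- max(abs(unlist(s@details))) + 1
  sh <- applyThreshold(s, thresholdPolicy("hard", threshold = big))
  expect_true(all(unlist(sh@details) == 0))
  expect_equal(approxCoeffs(sh), approxCoeffs(s))  # approximation untouched
  # reconstruction now equals the approximation-only image
  sz <- s
  sz@details <- lapply(sz@details, lapply, function(m) m * 0)
  expect_equal(idwt2(sh), idwt2(sz), tolerance = 1e-12)
})

test_that("hard threshold on the 2x2 haar fixture zeroes the small details", {
  s <- dwt2(matrix(c(1, 3, 2, 4), 2, 2), "haar")
  st <- applyThreshold(s, thresholdPolicy("hard", threshold = 1.5))
  expect_equal(as.vector(detailCoeffs(st, 1, "horizontal")), -2)
  expect_equal(as.vector(detailCoeffs(st, 1, "vertical")), 0)
  expect_equal(as.vector(detailCoeffs(st, 1, "diagonal")), 0)
  expect_equal(as.vector(approxCoeffs(st)), 5)
})

test_that("detail enhancement is the stated linear map with exact targeting", {
  x <- randomImage(16, 16, 12)
  s <- dwt2(x, "haar", levels = 2)

  sid <- enhanceDetails(s, enhanceParams(gain = 1, offset = 0))
  expect_equal(sid@details, s@details)

  s2 <- enhanceDetails(s, enhanceParams(gain = 2, offset = 1))
  expect_equal(detailCoeffs(s2, 1, "diagonal"),
               2 * detailCoeffs(s, 1, "diagonal") + 1)

  sz <- enhanceDetails(s, enhanceParams(gain = 0, offset = 0))
  expect_true(all(unlist(sz@details) == 0))

  # level/orientation targeting leaves everything else alone
  st <- enhanceDetails(s, enhanceParams(gain = 3, levels = 2,
                                        orientations = "horizontal"))
  expect_equal(detailCoeffs(st, 2, "horizontal"),
               3 * detailCoeffs(s, 2, "horizontal"))
  expect_equal(detailCoeffs(st, 1, "horizontal"),
               detailCoeffs(s, 1, "horizontal"))
  expect_equal(detailCoeffs(st, 2, "vertical"), detailCoeffs(s, 2, "vertical"))
  expect_equal(approxCoeffs(st), approxCoeffs(s))

  expect_error(enhanceDetails(s, enhanceParams(levels = 3)), "unknown level")
  expect_error(enhanceParams(orientations = "sideways"), "unknown orientation")
})
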