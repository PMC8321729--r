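test_that("haar dwt1 reproduces hand-computed coefficients", {
  d <- dwt1(c(1, 1, 1, 1), "haar")
  expect_equal(d$details[[1]], c(0, 0))

  d <- dwt1(c(1, 2, 3, 4), "haar")
  expect_equal(d$approx, c(3, 7) / sqrt(2))
  expect_equal(d$details[[1]], c(-1, -1) / sqrt(2))
  expect_equal(idwt1(d), c(1, 2, 3, 4), tolerance = 1e-12)
})

test_that("dwt1 agrees with the explicit Haar orthogonal-matrix oracle", {
  for (n in c(2, 4, 6, 8)) {
    set.seed(100 + n)
    x <- rnorm(n)
    H <- haarMatrixOracle(n)
    y <- as.vector(H %*% x)
    d <- dwt1(x, "haar")
    expect_lt(max(abs(d$approx - y[1:(n / 2)])), 1e-12)
    expect_lt(max(abs(d$details[[1]] - y[(n / 2 + 1):n])), 1e-12)
  }
})

test_that("2x2 haar dwt2 matches the brute-force oracle values", {
  x <- matrix(c(1, 3, 2, 4), 2, 2)  # rows (1,2) and (3,4)
  s <- dwt2(x, "haar", levels = 1)
  expect_equal(as.vector(approxCoeffs(s)), 5)
  expect_equal(as.vector(detailCoeffs(s, 1, "horizontal")), -2)
  expect_equal(as.vector(detailCoeffs(s, 1, "vertical")), -1)
  expect_equal(as.vector(detailCoeffs(s, 1, "diagonal")), 0)
  expect_equal(idwt2(s), x, tolerance = 1e-12)
})

test_that("dwt2 on even grids equals the separable Haar matrix oracle", {
  for (n in c(4, 8)) {
    x <- randomImage(n, n, seed = n)
    H <- haarMatrixOracle(n)
    Y <- H %*% x %*% t(H)           # [A H; V D] block layout
    k <- n / 2
    s <- dwt2(x, "haar", levels = 1)
    expect_lt(max(abs(approxCoeffs(s) - Y[1:k, 1:k])), 1e-12)
    expect_lt(max(abs(detailCoeffs(s, 1, "horizontal") -
                        Y[(k + 1):n, 1:k])), 1e-12)
    expect_lt(max(abs(detailCoeffs(s, 1, "vertical") -
                        Y[1:k, (k + 1):n])), 1e-12)
    expect_lt(max(abs(detailCoeffs(s, 1, "diagonal") -
                        Y[(k + 1):n, (k + 1):n])), 1e-12)
  }
})

test_that("constant images put all energy in the approximation", {
  x <- matrix(0.7, 9, 13)
  s <- dwt2(x, "haar", levels = 1)
  for (o in c("horizontal", "vertical", "diagonal"))
    expect_lt(max(abs(detailCoeffs(s, 1, o))), 1e-12)
  expect_lt(diff(range(approxCoeffs(s))), 1e-12)
  # zeroed details of a constant image reconstruct the same constant
  expect_equal(idwt2(s), x, tolerance = 1e-12)
})

test_that("round trip is exact across families, modes, levels and odd sizes", {
  cases <- expand.grid(w = c("haar", "db2", "db4"),
                       b = c("symmetric", "periodic", "zero"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    for (nr in c(16, 17)) {
      x <- randomImage(nr, 23, seed = i * 100 + nr)
      lev <- min(2, maxDwtLevels(c(nr, 23), waveletFilter(cases$w[i], cases$b[i])))
      s <- dwt2(x, cases$w[i], levels = lev, boundary = cases$b[i])
      expect_lt(max(abs(idwt2(s) - x)), 1e-10)
    }
  }
})

test_that("dwt2 is separable: rank-one row structure transforms like dwt1", {
  set.seed(5)
  r <- rnorm(32)
  x <- matrix(r, 16, 32, byrow = TRUE)   # every image row is the signal r
  s1 <- dwt1(r, "db4")
  s2 <- dwt2(x, "db4", levels = 1)
  # constant columns: subbands high-pass across rows vanish, and every row
  # of the approximation is dwt1(r)$approx times the column-pass DC gain
  expect_lt(max(abs(detailCoeffs(s2, 1, "horizontal"))), 1e-10)
  expect_lt(max(abs(detailCoeffs(s2, 1, "diagonal"))), 1e-10)
  ratio <- approxCoeffs(s2)[1, ] / s1$approx
  expect_equal(ratio, rep(ratio[1], length(ratio)), tolerance = 1e-8)
  expect_lt(max(abs(sweep(approxCoeffs(s2), 2, approxCoeffs(s2)[1, ]))), 1e-10)
})

test_that("transform is linear in the image", {
  x <- randomImage(12, 12, 1)
  y <- randomImage(12, 12, 2)
  sx <- dwt2(2.5 * x - 1.25 * y, "db2", levels = 2)
  s1 <- dwt2(x, "db2", levels = 2)
  s2 <- dwt2(y, "db2", levels = 2)
  expect_lt(max(abs(approxCoeffs(sx) -
                      (2.5 * approxCoeffs(s1) - 1.25 * approxCoeffs(s2)))), 1e-10)
  for (j in 1:2) for (o in c("horizontal", "vertical", "diagonal"))
    expect_lt(max(abs(detailCoeffs(sx, j, o) -
                        (2.5 * detailCoeffs(s1, j, o) -
                           1.25 * detailCoeffs(s2, j, o)))), 1e-10)
})

test_that("periodic-mode transform preserves energy (Parseval)", {
  for (w in c("haar", "db4")) {
    x <- randomImage(32, 24, seed = 9)
    s <- dwt2(x, w, levels = 2, boundary = "periodic")
    e <- sum(approxCoeffs(s)^2)
    for (j in 1:2) for (o in c("horizontal", "vertical", "diagonal"))
      e <- e + sum(detailCoeffs(s, j, o)^2)
    expect_equal(e, sum(x^2), tolerance = 1e-6)
  }
})

test_that("subband grids shrink by ceiling halving under the periodic mode", {
  x <- randomImage(21, 34, seed = 3)
  s <- dwt2(x, "haar", levels = 2, boundary = "periodic")
  expect_identical(dim(detailCoeffs(s, 1, "diagonal")), c(11L, 17L))
  expect_identical(dim(detailCoeffs(s, 2, "diagonal")), c(6L, 9L))
  expect_identical(originalDim(s), c(21L, 34L))
})

test_that("invalid decompositions fail with informative errors", {
  x <- randomImage(16, 16, 4)
  expect_error(dwt2(x, "db4", levels = 5), "maximum admissible level")
  expect_error(dwt2(array(0, c(4, 4, 2))), "2-D")
  expect_error(dwt1(matrix(1:4, 2)), "vector")
  expect_error(dwt2(x, "db4", levels = 0), "positive integer")

  s <- dwt2(x, "haar", levels = 2)
  s@details[[2]]$vertical <- s@details[[2]]$vertical[-1, , drop = FALSE]
  expect_error(idwt2(s), "level 2 vertical")
})

test_that("wavelet filter banks are orthonormal and well-formed", {
  for (nm in c("haar", "db2", "db4")) {
    w <- waveletFilter(nm)
    expect_equal(sum(recLo(w)^2), 1, tolerance = 1e-10)
    expect_equal(decLo(w), rev(recLo(w)))
    expect_equal(decHi(w), rev(recHi(w)))
    # low/high-pass shifts are mutually orthogonal
    L <- length(recLo(w))
    for (k in seq_len(L / 2 - 1))
      expect_lt(abs(sum(recLo(w)[1:(L - 2 * k)] * recLo(w)[(2 * k + 1):L])), 1e-10)
    expect_lt(abs(sum(recLo(w) * recHi(w))), 1e-10)
  }
  expect_equal(boundaryMode(waveletFilter("haar", "periodic")), "periodic")
})

test_that("subband CSV dump writes one readable grid per subband", {
  x <- randomImage(8, 8, 6)
  s <- dwt2(x, "haar", levels = 2)
  dir <- file.path(tempdir(), "subband-dump")
  paths <- writeSubbandCSV(s, dir)
  expect_length(paths, 7)  # 1 approx + 2 levels x 3 orientations
  back <- as.matrix(utils::read.csv(file.path(dir, "approx_L2.csv"),
                                    header = FALSE))
  expect_equal(unname(back), unname(approxCoeffs(s)), tolerance = 1e-10)
})
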