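test_that("quantization maps the 8-bit domain by fixed global scaling", {
  r <- IntensityRaster(matrix(c(0, 255, 128, 10), 2, 2), cellSize = 1)
  expect_equal(rasterValues(quantizeRaster(r, 16))[1, 1], 0)
  expect_equal(rasterValues(quantizeRaster(r, 16))[2, 1], 15)
  expect_equal(rasterValues(quantizeRaster(r, 4))[1, 2], 2)
  # out-of-range grey levels are rejected at the container boundary
  expect_error(IntensityRaster(matrix(300, 1, 1), cellSize = 1),
               "0, 255")
  expect_error(quantizeRaster(r, 1), "N must be")
})

test_that("the worked 4x4 co-occurrence example reproduces by hand", {
  img <- workedExampleImage()
  p <- GlcmParams(d = 1, theta = 0, N = 4, L = 4)
  g <- computeGlcm(img, p)
  expect_equal(g$nPairs, 12)
  expected <- matrix(0, 4, 4)
  expected[cbind(c(1, 1, 2, 3, 3, 4), c(1, 2, 2, 3, 4, 4))] <- 1 / 6
  expect_equal(g$P, expected)
  f <- glcmFeatures(g)
  expect_equal(unname(f["H"]), 5 / 6)
  expect_equal(unname(f["E"]), log(6))
  expect_equal(unname(f["muG"]), 4 / 3)
  expect_equal(unname(f["varG"]), 11 / 9)
})

test_that("masked pixels are excluded from pair tabulation", {
  img <- workedExampleImage()
  mask <- matrix(TRUE, 4, 4); mask[1, 1] <- FALSE
  p <- GlcmParams(d = 1, theta = 0, N = 4, L = 4)
  g <- computeGlcm(img, p, mask = mask)
  expect_equal(g$nPairs, 11)  # the (1,1)-(1,2) pair is gone
  expect_equal(sum(g$P), 1)
  expect_equal(g$V, oracleGlcm(replace(img, 1, NA), 1, 0, 4))
})

test_that("degenerate windows give the degenerate metrics", {
  p <- GlcmParams(d = 1, theta = 0, N = 8, L = 4)
  g <- computeGlcm(matrix(5, 4, 4), p)
  f <- glcmFeatures(g)
  expect_equal(unname(f["H"]), 1)
  expect_equal(unname(f["E"]), 0)
  expect_equal(unname(f["varG"]), 0)
  expect_equal(unname(f["muG"]), 5)
  expect_true(is.na(f["corrG"]))
  # uniform mass over k nonzero cells has entropy ln k
  P <- matrix(0, 4, 4); P[1, 1:4] <- 1 / 4
  expect_equal(unname(glcmFeatures(list(P = P))["E"]), log(4))
  # fully masked window signals zero countable pairs
  g0 <- computeGlcm(matrix(NA_real_, 4, 4), p)
  expect_equal(g0$nPairs, 0)
})

test_that("GLCMs equal exhaustive pair enumeration on random masked windows", {
  set.seed(9)
  for (rep in 1:12) {
    n <- sample(4:16, 1)
    N <- sample(c(4, 8, 16), 1)
    W <- matrix(sample(0:(N - 1), n * n, replace = TRUE), n, n)
    W[matrix(runif(n * n) < 0.2, n, n)] <- NA  # masked pixels
    d <- sample(1:3, 1)
    theta <- sample(c(0, 45, 90, 135), 1)
    sym <- sample(c(TRUE, FALSE), 1)
    p <- GlcmParams(d = d, theta = theta, N = N, L = n, symmetric = sym)
    g <- computeGlcm(W, p)
    V <- oracleGlcm(W, d, theta, N, symmetric = sym)
    expect_equal(g$V, V)
    if (sum(V) > 0) {
      expect_equal(sum(g$P), 1)
      expect_equal(unname(glcmFeatures(g)[c("E", "H", "muG", "varG")]),
                   unname(oracleGlcmMetrics(V / sum(V))))
    }
  }
})

test_that("homogeneity is 1 iff all mass is diagonal, and falls when mass moves off", {
  P <- diag(4) / 4
  expect_equal(unname(glcmFeatures(list(P = P))["H"]), 1)
  for (eps in c(0.05, 0.2, 0.4)) {
    Q <- diag(4) * (1 - eps) / 4
    Q[1, 4] <- eps
    expect_lt(glcmFeatures(list(P = Q))["H"], 1)
  }
  # entropy bounded by ln(N^2)
  N <- 5
  Pu <- matrix(1 / N^2, N, N)
  expect_equal(unname(glcmFeatures(list(P = Pu))["E"]), 2 * log(N))
})

test_that("the window lattice tiles without overlap under the coverage rule", {
  # 24x24 cells at 0.25 m with L = 3 m -> 2x2 lattice of 12-px windows
  r <- IntensityRaster(matrix(sample(0:255, 576, replace = TRUE), 24, 24),
                       cellSize = 0.25)
  tex <- slidingTextureGrid(r, GlcmParams(d = 5, L = 3, N = 16))
  w <- windowsTable(tex)
  expect_equal(nrow(w), 4)
  expect_equal(sort(unique(w$wrow)), c(0, 1))
  expect_setequal(w$row0, c(0, 12))

  # window count = floor(rows/L) * floor(cols/L) on a ragged raster
  r2 <- IntensityRaster(matrix(100, 30, 41), cellSize = 1)
  tex2 <- slidingTextureGrid(r2, GlcmParams(d = 1, L = 7, N = 8))
  expect_equal(nrow(windowsTable(tex2)), (30 %/% 7) * (41 %/% 7))

  # a 70%-valid window is undefined, a fully valid one defined
  v <- matrix(sample(0:255, 144, replace = TRUE), 12, 24)
  mask <- matrix(TRUE, 12, 24)
  mask[1:4, 1:11] <- FALSE  # left window coverage 100/144 < 0.75
  r3 <- IntensityRaster(v, mask, cellSize = 0.25)
  tex3 <- slidingTextureGrid(r3, GlcmParams(d = 2, L = 3, N = 16))
  w3 <- windowsTable(tex3)
  expect_true(is.na(w3$E[w3$wcol == 0]))
  expect_false(is.na(w3$E[w3$wcol == 1]))
  expect_lt(w3$coverage[w3$wcol == 0], 0.75)

  # fully valid constant raster: every window H = 1, E = 0
  r4 <- IntensityRaster(matrix(77, 24, 24), cellSize = 0.25)
  w4 <- windowsTable(slidingTextureGrid(r4, GlcmParams(d = 5, L = 3)))
  expect_true(all(w4$H == 1))
  expect_true(all(w4$E == 0))

  expect_error(slidingTextureGrid(r4, GlcmParams(d = 12, L = 3)),
               "exceed")
})

test_that("the parameter sweep enumerates the full grid and records failures", {
  r <- IntensityRaster(matrix(sample(0:255, 88 * 88, replace = TRUE),
                              88, 88), cellSize = 0.25)
  sw <- parameterSweep(r, dSet = c(1, 5, 8), thetaSet = c(0, 45, 90, 135),
                       LSet = c(2, 3, 5, 10, 20), N = 8)
  expect_equal(nrow(sw), 60)
  expect_equal(nrow(sw) * length(attr(sw, "metricSet")), 300)
  # L = 2 m (8 px) with d = 8 cannot form pairs: recorded, not fatal
  bad <- sw$d == 8 & sw$L == 2
  expect_true(all(nzchar(sw$error[bad])))
  expect_true(all(!nzchar(sw$error[!bad])))
  expect_error(parameterSweep(r, numeric(0), 0, 3), "non-empty")
})

test_that("reference angle has little effect on an isotropic texture", {
  set.seed(21)
  v <- matrix(sample(0:255, 96 * 96, replace = TRUE), 96, 96)
  r <- IntensityRaster(v, cellSize = 0.25)
  med <- sapply(c(0, 45, 90, 135), function(th) {
    w <- windowsTable(slidingTextureGrid(r, GlcmParams(d = 2, theta = th,
                                                       L = 3, N = 16)))
    median(w$E, na.rm = TRUE)
  })
  expect_lt(diff(range(med)), 0.1 * mean(med))
})
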