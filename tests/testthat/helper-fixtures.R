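# Shared fixtures, built in code. The full-size synthetic scene and its
# texture grid are computed once per test run and reused.

# the worked 4x4 example image: two-level blocks, d = 1, theta = 0
workedExampleImage <- function() {
  rbind(c(0, 0, 1, 1),
        c(0, 0, 1, 1),
        c(2, 2, 3, 3),
        c(2, 2, 3, 3))
}

smallScene <- function(seed = 11, nrow = 120, ncol = 60) {
  simulateEchogram(defaultSceneLayout(nrow = nrow, ncol = ncol),
                   seed = seed)
}

# planted class of each texture window (band of the window-centre row)
windowTruth <- function(tex, layout = defaultSceneLayout()) {
  w <- windowsTable(tex)
  Lpx <- w$row0[2] - w$row0[1]
  if (is.na(Lpx) || Lpx == 0) Lpx <- 12
  mid <- w$row0 + Lpx / 2
  layout$bands$class[findInterval(mid, c(layout$bands$row0 - 1,
                                         layout$bands$row1[3]))]
}

defaultSceneFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- simulateEchogram(seed = 101)
      r <- rasterizePolygons(sc$polys, sc$raster)$raster
      tex <- slidingTextureGrid(r, GlcmParams())
      calib <- buildCalibration(tex, sc$polys, B = 500, seed = 101)
      cache <<- list(scene = sc, raster = r, tex = tex, calib = calib,
                     truth = windowTruth(tex))
    }
    cache
  }
})

# small well-conditioned calibration matrix for unmixing tests
toyCalibration <- function(C = NULL) {
  if (is.null(C))
    C <- rbind(sand = c(E = 2.0, Hprime = 0.45, varG = 1.0),
               gravel = c(E = 4.2, Hprime = 0.87, varG = 30),
               boulders = c(E = 4.4, Hprime = 0.93, varG = 250))
  obj <- new("CalibrationMatrix")
  obj@C <- C
  obj@ciLow <- C
  obj@ciHigh <- C
  obj@classNames <- rownames(C)
  obj@featureNames <- colnames(C)
  obj@B <- 100; obj@level <- 0.95; obj@seed <- 1
  validObject(obj)
  obj
}

# standardized signature matrix (features x classes) matching the
# package's unmixing transform, derived directly from the printed rule
toyStandardized <- function(calib) {
  C <- calibrationValues(calib)
  mu <- colMeans(C)
  sdev <- apply(C, 2, sd)
  (t(C) - mu) / sdev
}

rectRing <- function(x0, x1, y0, y1) {
  cbind(c(x0, x1, x1, x0, x0), c(y0, y0, y1, y1, y0))
}
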