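# build a toy map directly on a window lattice
toyMap <- function(labels, classes = c("sand", "gravel", "boulders"),
                   spacing = 3) {
  n <- length(labels)
  w <- data.frame(wrow = seq_len(n) - 1L, wcol = 0L,
                  easting = 1.5,
                  northing = (n:1) * spacing - spacing / 2,
                  coverage = 1, label = labels, confidence = 1)
  new("ClassificationMap", windows = w, classes = classes, method = "lsq")
}

# one validation polygon per contiguous truth block
toyPolys <- function(truth, spacing = 3) {
  n <- length(truth)
  blocks <- rle(truth)
  ends <- cumsum(blocks$lengths)
  starts <- ends - blocks$lengths + 1
  rings <- lapply(seq_along(ends), function(b)
    rectRing(0, 3, (n - ends[b]) * spacing, (n - starts[b] + 1) * spacing))
  SubstratePolygonSet(rings, blocks$values,
                      rep("validation", length(ends)))
}

test_that("confusion matrices tally predictions inside labelled polygons", {
  truth <- rep(c("sand", "gravel", "boulders"), each = 10)
  perfect <- confusionMap(toyMap(truth), toyPolys(truth))
  expect_equal(unname(diag(perfect$rowPercent)), rep(100, 3))
  expect_equal(sum(perfect$counts), 30)

  nulls <- confusionMap(toyMap(rep("null", 30)), toyPolys(truth))
  expect_true(all(nulls$rowPercent[, "null"] == 100))
  expect_equal(unname(rowSums(nulls$rowPercent)), rep(100, 3))

  # planted label noise shows up as off-diagonal mass at the noise rate
  set.seed(6)
  truthBig <- rep(c("sand", "gravel", "boulders"), each = 200)
  noisy <- truthBig
  flip <- runif(600) < 0.1
  noisy[flip] <- sample(c("sand", "gravel", "boulders"), sum(flip),
                        replace = TRUE)
  cm <- confusionMap(toyMap(noisy), toyPolys(truthBig))
  off <- 1 - sum(diag(cm$counts)) / sum(cm$counts)
  expect_lt(abs(off - 0.1 * 2 / 3), 0.035)
  expect_error(confusionMap(toyMap(truth),
                            SubstratePolygonSet(list(rectRing(90, 91, 0, 1)),
                                                "sand", "validation")),
               "no overlap")
})

test_that("skill scores match explicit counting on small matrices", {
  cms <- list(
    matrix(c(8, 2, 3, 7), 2, 2, byrow = TRUE,
           dimnames = list(c("sand", "boulders"), c("sand", "boulders"))),
    matrix(c(50, 5, 5, 10, 20, 10, 2, 3, 45), 3, 3, byrow = TRUE,
           dimnames = list(c("sand", "gravel", "boulders"),
                           c("sand", "gravel", "boulders"))),
    matrix(c(12, 0, 0, 0, 0, 9, 1, 0, 2, 2, 6, 0), 3, 4, byrow = TRUE,
           dimnames = list(c("sand", "gravel", "boulders"),
                           c("sand", "gravel", "boulders", "null"))))
  for (counts in cms) {
    sk <- skillScores(list(counts = counts))
    for (cl in rownames(counts)) {
      o <- oracleSkill(counts[, setdiff(colnames(counts), "null"),
                              drop = FALSE], cl)
      row <- sk[sk$class == cl, ]
      # recall denominators include null predictions
      expect_equal(row$precision, unname(o["precision"]))
      expect_equal(row$recall, counts[cl, cl] / sum(counts[cl, ]))
      expect_equal(row$f1, f1Score(row$precision, row$recall))
    }
    macro <- sk[sk$class == "macro", ]
    expect_equal(macro$f1, mean(sk$f1[sk$class != "macro"]))
  }
  # harmonic-mean identities
  expect_equal(f1Score(0.5, 0.5), 0.5)
  for (x in c(0.2, 0.9)) expect_equal(f1Score(x, x), x)
  expect_equal(f1Score(0, 0), 0)
  expect_lte(f1Score(0.3, 0.9), (0.3 + 0.9) / 2)
})

test_that("areal fractions cover classified windows only and sum to 1", {
  hom <- toyMap(rep("sand", 12))
  expect_equal(unname(arealFractions(hom)), c(1, 0, 0))
  half <- toyMap(c(rep("sand", 6), rep("boulders", 4), "null", "nodata"))
  fr <- arealFractions(half)
  expect_equal(unname(fr), c(0.6, 0, 0.4))
  planted <- toyMap(c(rep("sand", 60), rep("gravel", 25),
                      rep("boulders", 15)))
  expect_equal(unname(arealFractions(planted)), c(0.60, 0.25, 0.15))
  expect_error(arealFractions(toyMap(rep("nodata", 3))), "no classified")
})

test_that("cumulative fractions converge and reduce to areal fractions", {
  flat <- assignDownstreamDistance(toyMap(rep("sand", 20)))
  cf <- cumulativeFractions(flat)
  expect_true(all(cf$fraction[cf$class == "sand"] == 1))

  # alternating equal bands: damped oscillation about 0.5, with the
  # closed-form prefix means
  alt <- assignDownstreamDistance(toyMap(rep(c("sand", "boulders"), 30)),
                                  track = cbind(c(1.5, 1.5), c(180, 0)))
  ca <- cumulativeFractions(alt)
  sandCurve <- ca$fraction[ca$class == "sand"]
  k <- seq_along(sandCurve)
  expect_equal(sandCurve, ceiling(k / 2) / k)
  expect_lt(abs(sandCurve[60] - 0.5), 0.01)
  tailBand <- sandCurve[k > 20]
  expect_true(all(abs(tailBand - 0.5) <= 0.05))

  # the final prefix equals the overall areal fractions
  mixed <- assignDownstreamDistance(
    toyMap(c(rep("sand", 9), rep("gravel", 6), rep("boulders", 5))))
  cm <- cumulativeFractions(mixed)
  final <- sapply(split(cm, cm$class),
                  function(d) d$fraction[which.max(d$distance)])
  af <- arealFractions(mixed)
  expect_equal(final[names(af)], af, ignore_attr = TRUE)

  noDist <- toyMap(rep("sand", 4))
  expect_error(cumulativeFractions(noDist), "distance")
})

test_that("downstream distances are monotone along the track order", {
  map <- toyMap(rep(c("sand", "gravel"), 10))
  withTrack <- assignDownstreamDistance(
    map, track = cbind(c(1.5, 1.5), c(60, 0)))
  d <- windowsTable(withTrack)$distance
  expect_true(all(diff(d) > 0))        # windows are listed north to south
  expect_equal(d[1], 0.5 * 3, tolerance = 1e-9)
  auto <- assignDownstreamDistance(map)
  da <- windowsTable(auto)$distance
  expect_true(all(diff(da) > 0) || all(diff(da) < 0))
})

test_that("map comparison reports fraction differences and agreement", {
  m <- toyMap(rep(c("sand", "gravel", "boulders"), each = 20))
  self <- compareMaps(m, m)
  expect_equal(unname(self$fractionDiff), rep(0, 3))
  expect_equal(self$agreement, 1)

  relab <- m
  w <- windowsTable(m)
  idx <- seq(1, 60, by = 20)  # relabel 3 of 60 windows (5%)
  w$label[idx] <- "boulders"
  relab@windows <- w
  cmp <- compareMaps(m, relab)
  expect_equal(cmp$agreement, 1 - 2 / 60)  # one flip was already boulders
  offLattice <- toyMap(rep("sand", 60))
  offLattice@windows$wcol <- 99L
  expect_error(compareMaps(m, offLattice), "disjoint")
})
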