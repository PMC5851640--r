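test_that("a single component recovers the sample moments under each structure", {
  set.seed(8)
  V <- cbind(rnorm(300, 2, 1.5), rnorm(300, -1, 0.5))
  n <- nrow(V)
  S <- cov(V) * (n - 1) / n
  for (st in c("full", "diag", "spherical", "tied")) {
    m <- fitGmm(V, q = 1, structure = st, init = "random", seed = 1)
    expect_equal(unname(componentMeans(m)[1, ]), unname(colMeans(V)),
                 tolerance = 1e-6)
    Sfit <- m@covariances[[1]]
    if (st %in% c("full", "tied")) {
      expect_equal(unname(Sfit), unname(S), tolerance = 1e-6)
    } else if (st == "diag") {
      expect_equal(diag(Sfit), unname(diag(S)), tolerance = 1e-6)
      expect_equal(Sfit[1, 2], 0)
    } else {
      expect_equal(Sfit[1, 1], Sfit[2, 2])
      expect_equal(Sfit[1, 1], mean(diag(S)), tolerance = 1e-6)
    }
  }
})

test_that("E-M recovers two separated 1-D components and keeps a monotone trace", {
  set.seed(10)
  V <- matrix(c(rnorm(500, 0, 1), rnorm(500, 10, 1)), ncol = 1)
  m <- fitGmm(V, q = 2, structure = "full", init = "random", seed = 4)
  mu <- sort(componentMeans(m)[, 1])
  expect_lt(abs(mu[1] - 0), 0.2)
  expect_lt(abs(mu[2] - 10), 0.2)
  expect_true(m@converged)
  tr <- logLikTrace(m)
  expect_true(all(diff(tr) >= -1e-8 * (abs(tr[-length(tr)]) + 1)))
  expect_equal(modelBic(m),
               -2 * m@logLik + gmmParameterCount(2, 1, "full") * log(1000))

  # tied structure shares one covariance object across components
  mt <- fitGmm(V, q = 2, structure = "tied", init = "random", seed = 4)
  expect_identical(mt@covariances[[1]], mt@covariances[[2]])
})

test_that("posteriors are stable, normalised and match the naive density oracle", {
  set.seed(12)
  means <- rbind(c(0, 0), c(6, 5), c(-4, 7))
  covs <- list(diag(2), matrix(c(2, 0.6, 0.6, 1), 2), 0.5 * diag(2))
  wts <- c(0.5, 0.3, 0.2)
  comp <- lapply(1:3, function(k)
    list(mean = means[k, ], cov = covs[[k]], weight = wts[k]))
  sim <- simulateFeatureMixture(comp, 600, seed = 3)
  m <- fitGmm(sim$V, q = 3, structure = "full", init = "means",
              initMeans = means)
  P <- gmmPosterior(m, sim$V)
  expect_equal(unname(rowSums(P)), rep(1, 600))
  for (i in sample(600, 25)) {
    expect_equal(P[i, ],
                 oraclePosterior(sim$V[i, ], m@weights, m@means,
                                 m@covariances),
                 tolerance = 1e-10)
  }
  # observation at a far component mean: posterior ~ 1 there
  pAt <- gmmPosterior(m, matrix(componentMeans(m)[2, ], 1))
  expect_gt(pAt[1, 2], 0.999)
  # symmetric two-component model: equidistant point splits 50/50
  m2 <- fitGmm(matrix(c(rnorm(400, -5), rnorm(400, 5)), ncol = 1),
               q = 2, structure = "tied", init = "means",
               initMeans = matrix(c(-5, 5), 2))
  pm <- gmmPosterior(m2, matrix(0, 1))
  expect_equal(pm[1, 1], 0.5, tolerance = 0.05)
})

test_that("maximised likelihood respects the structure nesting", {
  set.seed(17)
  V <- rbind(MASS::mvrnorm(300, c(0, 0), matrix(c(1, .5, .5, 2), 2)),
             MASS::mvrnorm(300, c(5, 4), diag(2)))
  ms <- fitGmm(V, q = 2, structure = "spherical", init = "random",
               seed = 2)
  rs <- gmmPosterior(ms, V)
  md <- fitGmm(V, q = 2, structure = "diag",
               init = "responsibilities", initResp = rs)
  rd <- gmmPosterior(md, V)
  mf <- fitGmm(V, q = 2, structure = "full",
               init = "responsibilities", initResp = rd)
  expect_gte(md@logLik, ms@logLik - 1e-6)
  expect_gte(mf@logLik, md@logLik - 1e-6)
})

test_that("free-parameter counts and BIC model search pick the planted model", {
  expect_equal(gmmParameterCount(3, 2, "full"),
               3 * 2 + 3 * 2 * 3 / 2 + 2)
  # q D + q D(D+1)/2 + (q-1) for full covariance
  expect_equal(gmmParameterCount(4, 3, "full"), 4 * 3 + 4 * 6 + 3)

  set.seed(30)
  V <- cbind(c(rnorm(250, 0, 1), rnorm(250, 8, 1)))
  colnames(V) <- "E"
  rank <- suppressWarnings(bicModelSearch(V, list("E"), qRange = 1:4,
                                          structures = "full", seed = 5))
  expect_equal(rank$q[1], 2)
  expect_true(all(diff(rank$bic[!is.na(rank$bic)]) >= 0))
})

test_that("cross-check: fitted parameters agree with an independent EM implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(19)
  V <- matrix(c(rnorm(400, 0, 1), rnorm(400, 6, 1.4)), ncol = 1)
  m <- fitGmm(V, q = 2, structure = "full", init = "random", seed = 9,
              tol = 1e-9)
  ref <- mclust::Mclust(as.numeric(V), G = 2, modelNames = "V",
                        verbose = FALSE)
  expect_equal(sort(componentMeans(m)[, 1]), sort(ref$parameters$mean),
               tolerance = 0.02, ignore_attr = TRUE)
  expect_equal(m@logLik, ref$loglik, tolerance = 1e-3)
})

test_that("components are labelled by grain-size order and calibration proximity", {
  calib <- toyCalibration()
  # q = 2 on E: low mean -> sand, high mean -> boulders
  m2 <- new("GmmModel", q = 2, structure = "full",
            means = matrix(c(1.0, 2.5), 2, 1,
                           dimnames = list(NULL, "E")),
            covariances = list(diag(1) * 0.1, diag(1) * 0.1),
            weights = c(0.5, 0.5), featureNames = "E", logLik = 0,
            logLikTrace = 0, bic = 0, nObs = 10, converged = TRUE,
            componentLabels = character(0), seed = 1)
  expect_equal(componentLabels(labelComponents(m2, calib)),
               c("sand", "boulders"))
  # q = 4: the two middle components are both gravel
  m4 <- m2
  m4@q <- 4
  m4@means <- matrix(c(260, 1.1, 30, 140), 4, 1,
                     dimnames = list(NULL, "varG"))
  m4@covariances <- rep(list(diag(1)), 4)
  m4@weights <- rep(0.25, 4)
  m4@featureNames <- "varG"
  expect_equal(componentLabels(labelComponents(m4, calib)),
               c("boulders", "sand", "gravel", "gravel"))
  # q = 3 at the calibration signatures: identity mapping
  m3 <- m2
  m3@q <- 3
  m3@means <- calibrationValues(calib)
  dimnames(m3@means) <- list(NULL, calibrationFeatures(calib))
  m3@covariances <- rep(list(diag(3)), 3)
  m3@weights <- rep(1, 3) / 3
  m3@featureNames <- calibrationFeatures(calib)
  expect_equal(componentLabels(labelComponents(m3, calib)),
               c("sand", "gravel", "boulders"))
})

test_that("the acceptance threshold produces the 'other' class as specified", {
  fx <- defaultSceneFixture()
  w <- windowsTable(fx$tex)
  ok <- !is.na(w$E)
  m2 <- fitGmm(as.matrix(w[ok, "E", drop = FALSE]), 2, "full",
               init = "means",
               initMeans = gmmInitMeansFromCalibration(fx$calib, "E", 2),
               featureNames = "E")
  m2 <- labelComponents(m2, fx$calib)
  res0 <- classifyGmm(fx$tex, m2, acceptanceThreshold = 0)
  expect_false(any(windowsTable(res0$map)$label == "other"))
  # with a 2-component model and threshold 0.6, posteriors (0.55, 0.45)
  # fall below it and the window reports "other"
  res <- classifyGmm(fx$tex, m2, acceptanceThreshold = 0.6)
  mw <- windowsTable(res$map)
  low <- ok & mw$confidence < 0.6
  expect_true(all(mw$label[low] == "other"))
  expect_true(all(mw$label[ok & mw$confidence >= 0.6] != "other"))
  # per-substrate posterior maps sum to 1 on defined windows
  post <- res$posterior
  sums <- rowSums(post[ok, paste0("post.",
                                  unique(componentLabels(m2)))])
  expect_equal(unname(sums), rep(1, sum(ok)))
})
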