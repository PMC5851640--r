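## Gaussian mixture model classification: E-M fitting with four
## covariance structures, BIC model search, substrate labelling,
## posterior maps.

logSumExpRows <- function(M) {
  mx <- apply(M, 1, max)
  mx + log(rowSums(exp(M - mx)))
}

# log N(v | mu, Sigma) for all rows of V; Sigma floored upstream
mvnLogDensity <- function(V, mu, Sigma) {
  D <- ncol(V)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- chol(Sigma + diag(1e-6, D))
  }
  dev <- sweep(V, 2, mu)
  z <- forwardsolve(t(ch), t(dev))
  -0.5 * D * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

# constrain a full covariance estimate to a structure; floor diagonal
constrainCov <- function(S, structure, floor = 1e-6) {
  D <- nrow(S)
  S <- switch(structure,
    full = S,
    diag = diag(pmax(diag(S), 0), D),
    spherical = diag(rep(mean(diag(S)), D), D),
    tied = S,  # pooling handled by the caller
    stop("unknown covariance structure"))
  diag(S) <- pmax(diag(S), floor)
  S
}

#' Free-parameter count of a GMM
#'
#' Means (`q D`) + covariance parameters per structure + mixing weights
#' (`q - 1`): full `q D(D+1)/2`, diag `q D`, spherical `q`, tied
#' `D(D+1)/2`.
#'
#' @param q components, D features, structure covariance structure.
#' @param D number of features.
#' @param structure one of "full", "diag", "spherical", "tied".
#' @return integer parameter count used in the BIC penalty.
#' @export
gmmParameterCount <- function(q, D, structure) {
  covPar <- switch(structure,
                   full = q * D * (D + 1) / 2,
                   diag = q * D,
                   spherical = q,
                   tied = D * (D + 1) / 2,
                   stop("unknown covariance structure"))
  as.integer(q * D + covPar + (q - 1))
}

# M-step from responsibilities R (n x q); returns weights, means, covs
gmmMStep <- function(V, R, structure, floor = 1e-6) {
  n <- nrow(V); D <- ncol(V); q <- ncol(R)
  Nk <- colSums(R)
  Nk <- pmax(Nk, 1e-10)
  wts <- Nk / sum(Nk)
  means <- t(R) %*% V / Nk
  covs <- vector("list", q)
  if (structure == "tied") {
    S <- matrix(0, D, D)
    for (k in seq_len(q)) {
      dev <- sweep(V, 2, means[k, ])
      S <- S + t(dev) %*% (dev * R[, k])
    }
    S <- S / sum(Nk)
    diag(S) <- pmax(diag(S), floor)
    for (k in seq_len(q)) covs[[k]] <- S
  } else {
    for (k in seq_len(q)) {
      dev <- sweep(V, 2, means[k, ])
      S <- t(dev) %*% (dev * R[, k]) / Nk[k]
      covs[[k]] <- constrainCov(S, structure, floor)
    }
  }
  list(weights = wts, means = means, covs = covs)
}

# E-step: responsibilities and log-likelihood under current parameters
gmmEStep <- function(V, wts, means, covs) {
  q <- length(wts)
  LD <- vapply(seq_len(q), function(k)
    log(wts[k]) + mvnLogDensity(V, means[k, ], covs[[k]]),
    numeric(nrow(V)))
  LD <- matrix(LD, nrow(V), q)
  lse <- logSumExpRows(LD)
  list(R = exp(LD - lse), logLik = sum(lse))
}

#' Fit a Gaussian mixture model by expectation-maximization
#'
#' Iterates E and M steps until the relative log-likelihood change drops
#' below `tol` or `maxIter` is reached. The log-likelihood is asserted
#' non-decreasing at every iteration (up to numerical fuzz) and the full
#' trace is kept. Initialization is either seeded random starting means
#' drawn from the data with pooled covariance (`init = "random"`, the
#' uninitialized mode used during model search so the search is not
#' steered toward one particular solution), supplied component means
#' (`init = "means"`), or supplied responsibilities
#' (`init = "responsibilities"`). Vanishing components and singular
#' covariances are re-regularised with a diagonal floor and a warning.
#'
#' @param V numeric matrix (or vector) of feature vectors, one row per
#'   observation.
#' @param q number of components (>= 1).
#' @param structure "full", "diag", "spherical" or "tied".
#' @param init "random", "means" or "responsibilities".
#' @param initMeans q x D matrix of starting means (init = "means").
#' @param initResp n x q responsibility matrix (init =
#'   "responsibilities").
#' @param tol relative log-likelihood convergence tolerance.
#' @param maxIter iteration cap.
#' @param seed RNG seed for random initialization.
#' @param covFloor diagonal covariance floor.
#' @param featureNames optional feature names (defaults to V's
#'   colnames).
#' @return a [GmmModel-class].
#' @export
fitGmm <- function(V, q, structure = c("full", "diag", "spherical", "tied"),
                   init = c("random", "means", "responsibilities"),
                   initMeans = NULL, initResp = NULL, tol = 1e-6,
                   maxIter = 300, seed = NULL, covFloor = 1e-6,
                   featureNames = NULL) {
  structure <- match.arg(structure)
  init <- match.arg(init)
  if (is.vector(V)) V <- matrix(V, ncol = 1)
  V <- as.matrix(V)
  n <- nrow(V); D <- ncol(V)
  if (q < 1) stop("q must be >= 1")
  if (n < q * (D + 1)) stop("too few observations for ", q, " components")
  if (is.null(featureNames))
    featureNames <- if (!is.null(colnames(V))) colnames(V) else
      paste0("f", seq_len(D))

  if (init == "random") {
    # seeded random draw of q observations as starting means (with the
    # pooled covariance), distance-weighted so the draws spread over the
    # data: data-blind but symmetry-breaking. Near-uniform random
    # responsibilities would start at the symmetric E-M fixed point
    # (all components at the global moments) and stall there.
    if (!is.null(seed)) set.seed(seed)
    # seeding distances in per-feature standardized space so no feature's
    # scale dominates; the fit itself runs on the raw features
    sds <- apply(V, 2, sd)
    sds[sds == 0] <- 1
    Vs <- sweep(V, 2, sds, "/")
    idx <- integer(q)
    idx[1] <- sample.int(n, 1)
    if (q > 1) {
      d2 <- rowSums(sweep(Vs, 2, Vs[idx[1], ])^2)
      for (k in 2:q) {
        idx[k] <- if (sum(d2) > 0) {
          sample.int(n, 1, prob = d2 / sum(d2))
        } else sample.int(n, 1)
        d2 <- pmin(d2, rowSums(sweep(Vs, 2, Vs[idx[k], ])^2))
      }
    }
    S0 <- constrainCov(cov(V) * (n - 1) / n,
                       if (structure == "tied") "full" else structure,
                       covFloor)
    par <- list(weights = rep(1 / q, q),
                means = V[idx, , drop = FALSE],
                covs = replicate(q, S0, simplify = FALSE))
  } else if (init == "means") {
    if (is.null(initMeans)) stop("initMeans required for init = 'means'")
    initMeans <- matrix(initMeans, nrow = q)
    S0 <- constrainCov(cov(V) * (n - 1) / n,
                       if (structure == "tied") "full" else structure,
                       covFloor)
    par <- list(weights = rep(1 / q, q), means = initMeans,
                covs = replicate(q, S0, simplify = FALSE))
  } else {
    if (is.null(initResp)) stop("initResp required")
    par <- gmmMStep(V, initResp, structure, covFloor)
  }

  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    es <- gmmEStep(V, par$weights, par$means, par$covs)
    ll <- es$logLik
    if (!is.finite(ll)) stop("log-likelihood diverged")
    if (ll < prev - 1e-8 * (abs(prev) + 1))
      stop("E-M log-likelihood decreased: ", prev, " -> ", ll)
    trace <- c(trace, ll)
    if (is.finite(prev) && abs(ll - prev) < tol * (abs(prev) + 1e-12)) {
      converged <- TRUE
      break
    }
    prev <- ll
    par <- gmmMStep(V, es$R, structure, covFloor)
    if (any(par$weights < 1e-8)) {
      warning("degenerate component (vanishing weight); re-regularised")
      par$weights <- pmax(par$weights, 1e-8)
      par$weights <- par$weights / sum(par$weights)
    }
  }
  k <- gmmParameterCount(q, D, structure)
  bic <- -2 * trace[length(trace)] + k * log(n)
  new("GmmModel", q = q, structure = structure,
      means = matrix(par$means, q, D,
                     dimnames = list(NULL, featureNames)),
      covariances = par$covs, weights = as.numeric(par$weights),
      featureNames = featureNames, logLik = trace[length(trace)],
      logLikTrace = trace, bic = bic, nObs = n, converged = converged,
      componentLabels = character(0),
      seed = if (is.null(seed)) NA_real_ else seed)
}

#' Posterior component probabilities (responsibilities)
#'
#' The probability each mixture component generated each observation,
#' computed in log space for stability; rows sum to 1.
#'
#' @param model a fitted [GmmModel-class].
#' @param V feature matrix (or vector), columns in model feature order.
#' @return n x q matrix of posteriors.
#' @export
gmmPosterior <- function(model, V) {
  if (is.null(dim(V))) V <- matrix(V, ncol = ncol(model@means))
  V <- as.matrix(V)
  gmmEStep(V, model@weights, model@means, model@covariances)$R
}

#' BIC model search over feature subsets, component counts and structures
#'
#' Fits uninitialized (seeded random-responsibility) mixtures for every
#' combination of feature subset, component count and covariance
#' structure, and ranks them by BIC (ascending). Fit failures are
#' recorded and excluded from the ranking.
#'
#' @param V named feature matrix (all candidate features as columns).
#' @param featureSubsets list of character vectors of column names.
#' @param qRange component counts to try (default 1:5).
#' @param structures covariance structures to try (default all four).
#' @param seed base seed; each combination uses a distinct derived seed.
#' @param nStarts random restarts per combination; the best
#'   log-likelihood fit is kept (default 3).
#' @param ... further arguments to [fitGmm()].
#' @return data.frame sorted by BIC with columns features, q, structure,
#'   bic, logLik, converged, error, and a `model` list-column.
#' @export
bicModelSearch <- function(V, featureSubsets, qRange = 1:5,
                           structures = c("full", "diag", "spherical",
                                          "tied"),
                           seed = 1, nStarts = 3, ...) {
  V <- as.matrix(V)
  combos <- expand.grid(subset = seq_along(featureSubsets), q = qRange,
                        structure = structures,
                        stringsAsFactors = FALSE)
  res <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    feats <- featureSubsets[[combos$subset[i]]]
    fit <- NULL
    for (s in seq_len(nStarts)) {
      one <- tryCatch(
        fitGmm(V[, feats, drop = FALSE], q = combos$q[i],
               structure = combos$structure[i], init = "random",
               seed = seed + 1000L * i + s, featureNames = feats, ...),
        error = function(e) e)
      if (inherits(one, "error")) {
        if (is.null(fit)) fit <- one
      } else if (is.null(fit) || inherits(fit, "error") ||
                 one@logLik > fit@logLik) {
        fit <- one
      }
    }
    failed <- inherits(fit, "error")
    res[[i]] <- data.frame(
      features = paste(feats, collapse = "+"), q = combos$q[i],
      structure = combos$structure[i],
      bic = if (failed) NA_real_ else fit@bic,
      logLik = if (failed) NA_real_ else fit@logLik,
      converged = if (failed) NA else fit@converged,
      error = if (failed) conditionMessage(fit) else "")
    res[[i]]$model <- if (failed) list(NULL) else list(fit)
  }
  out <- do.call(rbind, res)
  out[order(is.na(out$bic), out$bic), , drop = FALSE]
}

#' Initial component means derived from calibration signatures
#'
#' For a mean-initialized fit: `q` equal to the number of calibration
#' classes uses the signature rows directly; `q = 2` uses the extreme
#' classes (sand, boulders); `q = 4` with three classes splits gravel
#' into two components initialized at the midpoints between the gravel
#' signature and each neighbouring class signature (fine and coarse
#' gravel).
#'
#' @param calib a [CalibrationMatrix-class] with classes ordered by grain
#'   size.
#' @param features feature subset (columns of the signature matrix).
#' @param q component count (2, 4, or the number of classes).
#' @return q x length(features) matrix of starting means.
#' @export
gmmInitMeansFromCalibration <- function(calib, features, q) {
  C <- calib@C[, features, drop = FALSE]
  K <- nrow(C)
  if (q == K) return(unname(C))
  if (q == 2) return(unname(C[c(1, K), , drop = FALSE]))
  if (q == 4 && K == 3) {
    return(unname(rbind(C[1, ],
                        (C[1, ] + C[2, ]) / 2,
                        (C[2, ] + C[3, ]) / 2,
                        C[3, ])))
  }
  stop("no calibration-based initialization for q = ", q, " with ", K,
       " classes")
}

#' Assign substrate labels to mixture components
#'
#' Components are sorted by their mean along the calibration feature most
#' strongly associated with grain-size order (largest rank correlation
#' between the calibration class order and the signature values, sign
#' respected). `q = 2` maps the sorted components to the extreme classes
#' (sand, boulders); `q = 4` maps them to (sand, gravel, gravel,
#' boulders), the two middle components jointly representing gravel;
#' any other q assigns each component to the nearest calibration
#' signature (spread-standardized distance over the shared features).
#' Exactly equal means tie-break by component index with a warning.
#'
#' @param model a fitted [GmmModel-class].
#' @param calib a [CalibrationMatrix-class] with classes ordered by grain
#'   size.
#' @return the model with `componentLabels` filled.
#' @export
labelComponents <- function(model, calib) {
  feats <- intersect(model@featureNames, calib@featureNames)
  if (!length(feats)) stop("model and calibration share no features")
  K <- length(calib@classNames)
  rk <- vapply(feats, function(f)
    suppressWarnings(cor(seq_len(K), calib@C[, f], method = "spearman")),
    numeric(1))
  rk[is.na(rk)] <- 0
  dominant <- feats[which.max(abs(rk))]
  direction <- if (rk[which.max(abs(rk))] >= 0) 1 else -1
  m <- model@means[, dominant] * direction
  if (anyDuplicated(m))
    warning("components with equal means along '", dominant,
            "'; tie-break by component index")
  ord <- order(m, seq_along(m))
  labels <- character(model@q)
  if (model@q == 2) {
    labels[ord] <- calib@classNames[c(1, K)]
  } else if (model@q == 4 && K == 3) {
    labels[ord] <- calib@classNames[c(1, 2, 2, 3)]
  } else {
    std <- standardizedSignatures(calib)   # features x classes
    A <- std$A[match(feats, calib@featureNames), , drop = FALSE]
    for (k in seq_len(model@q)) {
      z <- (model@means[k, feats] - std$mu[feats]) / std$sd[feats]
      labels[k] <- calib@classNames[which.min(colSums((A - z)^2))]
    }
  }
  model@componentLabels <- labels
  model
}

#' Classify a texture grid with a labelled GMM
#'
#' Each defined window is labelled with the substrate of its
#' maximum-posterior component; windows whose maximum component
#' posterior falls below `acceptanceThreshold` are labelled "other".
#' Per-substrate posterior maps are the sums of member-component
#' posteriors (so the two gravel components of a 4-part model report as
#' one gravel class).
#'
#' @param tex a [TextureGrid-class].
#' @param model a [GmmModel-class] with component labels assigned.
#' @param acceptanceThreshold posterior acceptance threshold (default
#'   0.6; 0 disables the "other" class).
#' @return list with `map` (a [ClassificationMap-class]) and `posterior`
#'   (data.frame of per-component and per-substrate posteriors per
#'   window).
#' @export
classifyGmm <- function(tex, model, acceptanceThreshold = 0.6) {
  if (!length(model@componentLabels))
    stop("model components are unlabelled; call labelComponents() first")
  if (!all(model@featureNames %in% names(tex@windows)))
    stop("model features missing from the texture grid")
  w <- tex@windows
  n <- nrow(w)
  defined <- !is.na(w$E)
  substrates <- unique(model@componentLabels)
  P <- matrix(NA_real_, n, model@q)
  label <- rep("nodata", n)
  conf <- rep(NA_real_, n)
  if (any(defined)) {
    V <- as.matrix(w[defined, model@featureNames, drop = FALSE])
    P[defined, ] <- gmmPosterior(model, V)
    mx <- max.col(P[defined, , drop = FALSE], ties.method = "first")
    top <- P[defined, , drop = FALSE][cbind(seq_along(mx), mx)]
    lab <- model@componentLabels[mx]
    lab[top < acceptanceThreshold] <- "other"
    label[defined] <- lab
    conf[defined] <- top
  }
  S <- vapply(substrates, function(s)
    rowSums(P[, model@componentLabels == s, drop = FALSE]),
    numeric(n))
  S <- matrix(S, n, length(substrates),
              dimnames = list(NULL, substrates))
  post <- cbind(w[, c("wrow", "wcol", "easting", "northing")],
                setNames(as.data.frame(P),
                         paste0("comp", seq_len(model@q))),
                setNames(as.data.frame(S), paste0("post.", substrates)))
  mapWin <- cbind(w[, c("wrow", "wcol", "easting", "northing",
                        "coverage")],
                  label = label, confidence = conf,
                  setNames(as.data.frame(S), paste0("post.", substrates)))
  map <- new("ClassificationMap", windows = mapWin,
             classes = substrates, method = "gmm")
  list(map = map, posterior = post,
       acceptanceThreshold = acceptanceThreshold)
}

#' Serialize a GMM as JSON
#'
#' @param model a [GmmModel-class].
#' @param path JSON path.
#' @export
writeGmmModel <- function(model, path) {
  jsonlite::write_json(list(
    q = model@q, structure = model@structure, means = model@means,
    covariances = model@covariances, weights = model@weights,
    featureNames = model@featureNames, logLik = model@logLik,
    bic = model@bic, componentLabels = model@componentLabels,
    seed = model@seed), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
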