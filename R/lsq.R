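## Linear least-squares unmixing classifier.

# z-score features by the calibration spread so E, Hprime and varG
# contribute comparably; returns features x classes signature matrix and
# the transform
standardizedSignatures <- function(calib) {
  C <- calib@C                      # classes x features
  mu <- colMeans(C)
  sdev <- apply(C, 2, sd)
  sdev[sdev == 0] <- 1
  A <- (t(C) - mu) / sdev           # features x classes
  list(A = A, mu = mu, sd = sdev)
}

# abundance-sum-constraint weight for the augmented NNLS system: strong
# enough that sum(f) is held at 1 (fully constrained unmixing), so the
# mixing proportions are unique even though centering leaves the
# signature matrix with the all-ones null direction
ascWeight <- 10

#' Unmix a feature vector against the calibration signatures
#'
#' Solves the fully constrained non-negative least-squares mixing
#' problem: `min_f || A f - o ||^2, f >= 0` with a weighted
#' abundance-sum row holding `sum(f)` at 1, where the columns of A are
#' the class signatures and o the observed window features, both
#' z-scored by the calibration spread. The result is normalised,
#' `u = f / sum(f)`: the per-class proportion of variance explained. If
#' all coefficients are zero, u is uniform.
#'
#' @param o named numeric feature vector (must cover the calibration
#'   features).
#' @param calib a [CalibrationMatrix-class].
#' @return named numeric u (per class), non-negative, summing to 1.
#' @export
lsqUnmix <- function(o, calib) {
  std <- standardizedSignatures(calib)
  K <- ncol(std$A)
  Aaug <- rbind(std$A, rep(ascWeight, K))
  if (qr(Aaug)$rank < K)
    warning("calibration matrix is rank deficient; unmixing is ill-conditioned")
  ov <- (as.numeric(o[calib@featureNames]) - std$mu) / std$sd
  if (any(!is.finite(ov))) stop("observed feature vector is not finite")
  f <- pracma::lsqnonneg(Aaug, c(ov, ascWeight))$x
  u <- if (sum(f) > 0) f / sum(f) else rep(1 / K, K)
  setNames(u, calib@classNames)
}

#' Confidence of each sediment type from its unmixing proportions
#'
#' The literal confidence rule `alpha_q = u_q / sum_{n != q} (1 - u_n)`;
#' with `sum(u) = 1` this equals `u_q / (q - 2 + u_q)`. Uniform u maps
#' every alpha to 1/4 at q = 3, the indeterminate boundary. 0/0 (q = 2
#' with u_q = 0) is defined as 0.
#'
#' @param u non-negative proportions summing to 1 (length >= 2).
#' @return alpha, same length and names as u.
#' @export
lsqConfidence <- function(u) {
  q <- length(u)
  if (q < 2) stop("confidence is undefined for fewer than 2 classes")
  if (any(u < -1e-9) || abs(sum(u) - 1) > 1e-6)
    stop("u must be non-negative and sum to 1")
  den <- vapply(seq_len(q), function(k) sum(1 - u[-k]), numeric(1))
  alpha <- ifelse(den > 0, u / den, 0)
  setNames(alpha, names(u))
}

#' Indeterminate-band membership
#'
#' TRUE when every confidence lies strictly inside the open band; the
#' comparison carries a 1e-9 tolerance so values that are exactly on a
#' boundary up to floating-point rounding (e.g. alpha = 1/4 at q = 3
#' under uniform u) are treated as on the boundary, not inside.
#'
#' @param alpha confidence vector.
#' @param band open interval c(lower, upper).
#' @return logical scalar.
#' @export
inIndeterminateBand <- function(alpha, band) {
  tol <- 1e-9
  all(alpha > band[1] + tol & alpha < band[2] - tol)
}

# weighted unmixing proportions: u'_q proportional to w_q * u_q
applyWeights <- function(u, w) {
  uw <- u * w
  if (sum(uw) > 0) uw / sum(uw) else rep(1 / length(u), length(u))
}

#' Classify a texture grid with the LSQ unmixing model
#'
#' Per defined window: unmix the window's features against the
#' calibration, apply the class weights (`u' proportional to w * u`,
#' renormalised), compute confidences alpha, and label with the
#' highest-confidence class - unless every alpha falls strictly inside
#' the open indeterminate band, in which case the window gets the null
#' class. Windows without defined features are nodata.
#'
#' @param tex a [TextureGrid-class].
#' @param model an [LsqModel-class].
#' @return a [ClassificationMap-class]; the windows table carries
#'   per-class `u.<class>` and `alpha.<class>` columns.
#' @export
classifyLsq <- function(tex, model) {
  calib <- model@calibration
  if (!all(calib@featureNames %in% names(tex@windows)))
    stop("model features missing from the texture grid")
  w <- tex@windows
  classes <- calib@classNames
  n <- nrow(w)
  U <- A <- matrix(NA_real_, n, length(classes),
                   dimnames = list(NULL, classes))
  label <- rep("nodata", n)
  conf <- rep(NA_real_, n)
  defined <- which(!is.na(w$E))
  for (i in defined) {
    o <- unlist(w[i, calib@featureNames])
    u <- applyWeights(lsqUnmix(o, calib), model@weights)
    a <- lsqConfidence(u)
    U[i, ] <- u; A[i, ] <- a
    if (inIndeterminateBand(a, model@band)) {
      label[i] <- "null"
      conf[i] <- max(a)
    } else {
      k <- which.max(a)             # ties: first class wins
      label[i] <- classes[k]
      conf[i] <- a[k]
    }
  }
  out <- cbind(w[, c("wrow", "wcol", "easting", "northing", "coverage")],
               label = label, confidence = conf,
               setNames(as.data.frame(U), paste0("u.", classes)),
               setNames(as.data.frame(A), paste0("alpha.", classes)))
  new("ClassificationMap", windows = out, classes = classes,
      method = "lsq")
}

#' Enumerate the weight simplex at a fixed increment
#'
#' All q-part weight vectors with entries that are multiples of
#' `increment` and sum to 1, in lexicographic order.
#'
#' @param increment grid step (1/increment must be a whole number).
#' @param q number of classes.
#' @return matrix with one weight vector per row.
#' @export
enumerateWeightGrid <- function(increment, q) {
  m <- round(1 / increment)
  if (abs(m * increment - 1) > 1e-9) stop("1/increment must be whole")
  compose <- function(total, parts) {
    if (parts == 1) return(matrix(total, 1, 1))
    do.call(rbind, lapply(0:total, function(i)
      cbind(i, compose(total - i, parts - 1))))
  }
  unname(compose(m, q) / m)
}

#' Optimize LSQ class weights on labelled windows
#'
#' Exhaustive search over the weight simplex at the given increment,
#' maximising the unweighted mean of per-class accuracies (balanced
#' accuracy) against the polygon labels. The uniform weight vector is
#' evaluated first and the grid then scanned in lexicographic order,
#' replacing the incumbent only on strict improvement, so ties resolve
#' deterministically (and to equal weights when those already achieve
#' the maximum).
#'
#' @param tex a [TextureGrid-class].
#' @param polys labelled polygons; `roles` selects which are used as
#'   truth.
#' @param model an [LsqModel-class] (calibration and band are used).
#' @param increment weight grid step (default 0.1).
#' @param roles polygon roles treated as truth (default calibration).
#' @return list with `weights` (the optimum), `objective` (balanced
#'   accuracy) and `table` (objective per evaluated weight vector).
#' @export
optimizeWeights <- function(tex, polys, model, increment = 0.1,
                            roles = "calibration") {
  calib <- model@calibration
  classes <- calib@classNames
  w <- tex@windows
  cls <- assignWindowClasses(tex, polys, roles = roles)
  keep <- !is.na(w$E) & !is.na(cls)
  if (!any(keep)) stop("no labelled windows with defined features")
  truth <- cls[keep]
  if (!all(classes %in% truth))
    warning("not every class is represented among labelled windows")
  U <- t(vapply(which(keep), function(i)
    lsqUnmix(unlist(w[i, calib@featureNames]), calib),
    numeric(length(classes))))
  balAcc <- function(wt) {
    Uw <- U * rep(wt, each = nrow(U))
    s <- rowSums(Uw)
    Uw[s > 0, ] <- Uw[s > 0, ] / s[s > 0]
    Uw[s == 0, ] <- 1 / length(classes)
    den <- (length(classes) - 2) + Uw   # alpha denominator, q - 2 + u
    Aw <- Uw / den
    tol <- 1e-9
    indet <- rowSums(Aw > model@band[1] + tol &
                       Aw < model@band[2] - tol) == length(classes)
    pred <- classes[max.col(Aw, ties.method = "first")]
    pred[indet] <- "null"
    mean(vapply(classes, function(cl) {
      idx <- truth == cl
      if (!any(idx)) return(NA_real_)
      mean(pred[idx] == cl)
    }, numeric(1)), na.rm = TRUE)
  }
  grid <- enumerateWeightGrid(increment, length(classes))
  cand <- rbind(rep(1 / length(classes), length(classes)), grid)
  obj <- apply(cand, 1, balAcc)
  best <- 1
  for (i in seq_along(obj)) if (obj[i] > obj[best] + 1e-12) best <- i
  list(weights = setNames(cand[best, ], classes), objective = obj[best],
       table = data.frame(cand, objective = obj))
}

#' Serialize an LSQ model as JSON
#'
#' @param model an [LsqModel-class].
#' @param path JSON path.
#' @export
writeLsqModel <- function(model, path) {
  jsonlite::write_json(list(
    calibration = list(classNames = model@calibration@classNames,
                       featureNames = model@calibration@featureNames,
                       C = model@calibration@C,
                       ciLow = model@calibration@ciLow,
                       ciHigh = model@calibration@ciHigh,
                       B = model@calibration@B,
                       level = model@calibration@level,
                       seed = model@calibration@seed),
    weights = as.list(model@weights), band = model@band),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
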