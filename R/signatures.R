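## First-order zonal signatures and the bootstrapped-median calibration
## matrix.

#' First-order zonal statistics per substrate class
#'
#' Pools raw intensity values across all patches of each class (aggregated,
#' not per-patch means of means) and reports central tendency and shape
#' statistics: mean, sigma, CV = sigma/mean, quartiles, excess (Fisher)
#' kurtosis and standardized skewness, plus the patch count.
#'
#' @param raster an [IntensityRaster-class].
#' @param polys a [SubstratePolygonSet-class]; polygons with roles in
#'   `roles` contribute, exclusions are applied first.
#' @param roles polygon roles to pool (default calibration + validation).
#' @return data.frame with one row per class: class, mean, sigma, cv,
#'   q25, q50, q75, kurtosis, skewness, nPatches, nCells.
#' @export
zonalFirstOrder <- function(raster, polys,
                            roles = c("calibration", "validation")) {
  rz <- rasterizePolygons(polys, raster, roles = roles)
  classes <- intersect(polys@vocabulary, unique(polys@labels))
  out <- lapply(classes, function(cl) {
    v <- rz$raster@values[!is.na(rz$labels) & rz$labels == cl]
    v <- v[!is.na(v)]
    if (!length(v))
      stop("class '", cl, "' has zero valid cells under its polygons")
    data.frame(class = cl, mean = mean(v), sigma = sd(v),
               cv = sd(v) / mean(v),
               q25 = unname(quantile(v, 0.25)),
               q50 = unname(quantile(v, 0.50)),
               q75 = unname(quantile(v, 0.75)),
               kurtosis = e1071::kurtosis(v, type = 1),
               skewness = e1071::skewness(v, type = 1),
               nPatches = sum(polys@labels == cl &
                                polys@roles %in% roles),
               nCells = length(v))
  })
  do.call(rbind, out)
}

#' Percentile bootstrap of the median
#'
#' Resamples with replacement `B` times; the point estimate is the sample
#' median and the interval the percentile bootstrap interval of the
#' replicate medians. Bit-reproducible given `seed`.
#'
#' @param values numeric sample (length >= 2 for a meaningful interval).
#' @param B bootstrap replicates (>= 100; default 10000).
#' @param level confidence level (default 0.95).
#' @param seed optional integer seed.
#' @return list with `median`, `ciLow`, `ciHigh`.
#' @export
bootstrapMedian <- function(values, B = 10000, level = 0.95, seed = NULL) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty sample")
  if (B < 100) stop("B must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  meds <- vapply(seq_len(B),
                 function(i) median(values[sample.int(n, n, replace = TRUE)]),
                 numeric(1))
  a <- (1 - level) / 2
  ci <- unname(quantile(meds, c(a, 1 - a), type = 7))
  est <- median(values)
  # the sample median can graze a percentile bound by floating fuzz only
  list(median = est, ciLow = min(ci[1], est), ciHigh = max(ci[2], est))
}

# slot name "C" would partially match new()'s Class argument, so the
# calibration container is filled by slot assignment
newCalibrationMatrix <- function(C, ciLow, ciHigh, classNames,
                                 featureNames, B, level, seed) {
  obj <- new("CalibrationMatrix")
  obj@C <- C; obj@ciLow <- ciLow; obj@ciHigh <- ciHigh
  obj@classNames <- classNames; obj@featureNames <- featureNames
  obj@B <- B; obj@level <- level; obj@seed <- seed
  validObject(obj)
  obj
}

# window -> class assignment by centroid containment; later polygons win
assignWindowClasses <- function(tex, polys, roles = "calibration") {
  w <- tex@windows
  pts <- cbind(w$easting, w$northing)
  cls <- rep(NA_character_, nrow(w))
  for (i in seq_along(polys@polygons)) {
    if (!polys@roles[i] %in% roles) next
    inside <- pointsInRing(polys@polygons[[i]], pts)
    cls[inside] <- polys@labels[i]
  }
  # exclusions drop windows outright
  for (i in seq_along(polys@polygons)) {
    if (polys@roles[i] != "exclusion") next
    cls[pointsInRing(polys@polygons[[i]], pts)] <- NA_character_
  }
  cls
}

#' Build the bootstrapped-median calibration matrix
#'
#' Assigns each defined texture window to a substrate class by centroid
#' containment in the calibration polygons, then fills
#' `C[class, feature]` with the bootstrap median of that feature over the
#' class's windows (B replicates, percentile intervals). Homogeneity is
#' stored contrast-reversed as `Hprime = 1 - H` when requested, so all
#' signature features increase with grain size.
#'
#' @param tex a [TextureGrid-class].
#' @param polys a [SubstratePolygonSet-class] with calibration polygons.
#' @param features feature columns of the texture grid to use (default
#'   E, Hprime, varG).
#' @param B,level,seed bootstrap settings; per-cell seeds are derived
#'   deterministically from `seed`.
#' @return a [CalibrationMatrix-class] with classes ordered as in the
#'   polygon vocabulary.
#' @export
buildCalibration <- function(tex, polys,
                             features = c("E", "Hprime", "varG"),
                             B = 10000, level = 0.95, seed = 1) {
  w <- tex@windows
  cls <- assignWindowClasses(tex, polys, roles = "calibration")
  defined <- !is.na(w$E)
  classes <- intersect(polys@vocabulary, unique(cls[defined]))
  missing <- setdiff(intersect(polys@vocabulary,
                               polys@labels[polys@roles == "calibration"]),
                     classes)
  if (length(missing))
    stop("class(es) with no defined calibration windows: ",
         paste(missing, collapse = ", "))
  K <- length(classes); Fq <- length(features)
  C <- lo <- hi <- matrix(NA_real_, K, Fq,
                          dimnames = list(classes, features))
  for (k in seq_len(K)) {
    for (f in seq_len(Fq)) {
      v <- w[[features[f]]][defined & !is.na(cls) & cls == classes[k]]
      bs <- bootstrapMedian(v, B = B, level = level,
                            seed = seed + 1000L * k + f)
      C[k, f] <- bs$median; lo[k, f] <- bs$ciLow; hi[k, f] <- bs$ciHigh
    }
  }
  newCalibrationMatrix(C, lo, hi, classes, features, B, level, seed)
}

#' Serialize / restore a calibration matrix as JSON
#'
#' @param calib a [CalibrationMatrix-class].
#' @param path JSON file path.
#' @export
writeCalibration <- function(calib, path) {
  jsonlite::write_json(list(classNames = calib@classNames,
                            featureNames = calib@featureNames,
                            C = calib@C, ciLow = calib@ciLow,
                            ciHigh = calib@ciHigh, B = calib@B,
                            level = calib@level, seed = calib@seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  x <- jsonlite::fromJSON(path)
  dn <- list(x$classNames, x$featureNames)
  asMat <- function(m) matrix(unlist(m), length(dn[[1]]), length(dn[[2]]),
                              dimnames = dn)
  newCalibrationMatrix(asMat(x$C), asMat(x$ciLow), asMat(x$ciHigh),
                       x$classNames, x$featureNames, x$B, x$level, x$seed)
}
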