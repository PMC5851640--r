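#' @import methods
#' @importFrom stats median quantile sd var cov runif rnorm rpois sample.int prcomp setNames aggregate
#' @importFrom utils read.csv write.csv head tail
NULL

## Central S4 containers. Grid convention used everywhere:
## row-major matrices, row 1 = northernmost; cells addressed (row, col),
## 1-based inside R, 0-based in exported CSV; polygons are tested against
## cell centers.

#' Gridded side-scan intensity raster
#'
#' An 8-bit echogram on a regular grid. `values` holds grey levels in
#' \[0, 255\] (NA allowed where invalid); `validMask` marks cells carrying
#' data (water column, shadows and over-saturated nadir are typically
#' masked out). `origin` is the (easting, northing) of the outer corner of
#' cell (1, 1), i.e. the north-west corner of the grid.
#'
#' @slot values numeric matrix of grey levels.
#' @slot validMask logical matrix, same shape as `values`.
#' @slot cellSize cell edge length in metres (default 0.25).
#' @slot origin numeric(2): (easting, northing) of the NW grid corner.
#' @slot crsTag opaque CRS string, passed through untouched.
#' @export
setClass("IntensityRaster",
  representation(values = "matrix", validMask = "matrix",
                 cellSize = "numeric", origin = "numeric",
                 crsTag = "character"))

setValidity("IntensityRaster", function(object) {
  msg <- character()
  if (!all(dim(object@values) == dim(object@validMask)))
    msg <- c(msg, "values and validMask must have identical dimensions")
  if (length(object@cellSize) != 1 || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (length(object@origin) != 2 || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be two finite coordinates")
  v <- object@values[object@validMask]
  if (length(v) && (any(!is.finite(v)) || any(v < 0) || any(v > 255)))
    msg <- c(msg, "valid cells must hold finite grey levels in [0, 255]")
  if (nrow(object@values) < 1 || ncol(object@values) < 1)
    msg <- c(msg, "grid must be at least 1 x 1")
  if (length(msg)) msg else TRUE
})

#' Labeled substrate polygons
#'
#' Patch outlines digitised over the echogram, each carrying a substrate
#' class and a role: `calibration` (used to build signatures),
#' `validation` (used for skill evaluation) or `exclusion` (cells removed
#' from the valid mask, e.g. the over-saturated nadir stripe).
#'
#' @slot polygons list of two-column coordinate matrices (easting,
#'   northing), closed outer rings.
#' @slot labels character vector of class labels (one per polygon;
#'   exclusion polygons use "exclusion").
#' @slot roles character vector in {"calibration","validation","exclusion"}.
#' @slot vocabulary declared class vocabulary, ordered by grain size.
#' @export
setClass("SubstratePolygonSet",
  representation(polygons = "list", labels = "character",
                 roles = "character", vocabulary = "character"))

setValidity("SubstratePolygonSet", function(object) {
  msg <- character()
  n <- length(object@polygons)
  if (length(object@labels) != n || length(object@roles) != n)
    msg <- c(msg, "labels and roles must match the number of polygons")
  if (!all(object@roles %in% c("calibration", "validation", "exclusion")))
    msg <- c(msg, "roles must be calibration, validation or exclusion")
  bad <- !(object@labels %in% c(object@vocabulary, "exclusion"))
  if (any(bad))
    msg <- c(msg, paste0("unknown class label(s): ",
                         paste(unique(object@labels[bad]), collapse = ", ")))
  for (p in object@polygons) {
    if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 3 || any(!is.finite(p)))
      msg <- c(msg, "each polygon must be a finite n x 2 ring with >= 3 vertices")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' GLCM computation parameters
#'
#' @slot d search distance in pixels (>= 1).
#' @slot theta reference angle in degrees, one of 0, 45, 90, 135.
#' @slot L window width in metres.
#' @slot N number of grey levels after quantization (>= 2).
#' @slot symmetric add transpose pairs if TRUE (default FALSE: directed
#'   pairs at a single reference angle).
#' @slot coverageMin minimum fraction of valid cells for a window to be
#'   evaluated (default 0.75).
#' @export
setClass("GlcmParams",
  representation(d = "numeric", theta = "numeric", L = "numeric",
                 N = "numeric", symmetric = "logical",
                 coverageMin = "numeric"))

setValidity("GlcmParams", function(object) {
  msg <- character()
  if (object@d < 1 || object@d != round(object@d))
    msg <- c(msg, "d must be a whole number >= 1")
  if (!object@theta %in% c(0, 45, 90, 135))
    msg <- c(msg, "theta must be one of 0, 45, 90, 135")
  if (object@L <= 0) msg <- c(msg, "L must be positive")
  if (object@N < 2) msg <- c(msg, "N must be >= 2")
  if (object@coverageMin <= 0 || object@coverageMin > 1)
    msg <- c(msg, "coverageMin must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Per-window texture features on the tiling lattice
#'
#' One row per non-overlapping L x L window: lattice address, pixel
#' extent, centroid coordinates, coverage fraction, and the six GLCM
#' metrics (NA where coverage < coverageMin or no pixel pair was
#' countable).
#'
#' @slot windows data.frame with columns wrow, wcol, row0, col0, easting,
#'   northing, coverage, E, H, Hprime, muG, varG, corrG.
#' @slot params the [GlcmParams-class] used.
#' @slot windowPx window width in pixels.
#' @slot cellSize raster cell size (m).
#' @slot origin raster origin (NW corner).
#' @export
setClass("TextureGrid",
  representation(windows = "data.frame", params = "GlcmParams",
                 windowPx = "numeric", cellSize = "numeric",
                 origin = "numeric"))

#' Bootstrapped-median substrate signature matrix
#'
#' The calibration matrix C: one row per substrate class (ordered by grain
#' size), one column per texture feature, each entry the bootstrap median
#' of that feature over the class's calibration windows, with percentile
#' confidence bounds.
#'
#' @slot C classes x features numeric matrix of bootstrap medians.
#' @slot ciLow,ciHigh matching confidence bounds.
#' @slot classNames,featureNames dimension names.
#' @slot B bootstrap replicates.
#' @slot level confidence level.
#' @slot seed RNG seed recorded for reproducibility.
#' @export
setClass("CalibrationMatrix",
  representation(C = "matrix", ciLow = "matrix", ciHigh = "matrix",
                 classNames = "character", featureNames = "character",
                 B = "numeric", level = "numeric", seed = "numeric"))

setValidity("CalibrationMatrix", function(object) {
  msg <- character()
  if (any(!is.finite(object@C))) msg <- c(msg, "C must be finite")
  if (any(object@ciLow > object@C + 1e-12) ||
      any(object@ciHigh < object@C - 1e-12))
    msg <- c(msg, "medians must lie within their confidence bounds")
  if (length(msg)) msg else TRUE
})

#' Linear least-squares unmixing classifier
#'
#' @slot calibration the [CalibrationMatrix-class] of substrate signatures.
#' @slot weights per-class weights, non-negative, summing to 1.
#' @slot band open indeterminate interval on the confidence alpha
#'   (default (0.15, 0.25)): a window whose alphas all fall inside it is
#'   assigned the null class.
#' @export
setClass("LsqModel",
  representation(calibration = "CalibrationMatrix", weights = "numeric",
                 band = "numeric"))

setValidity("LsqModel", function(object) {
  msg <- character()
  if (any(object@weights < 0) || abs(sum(object@weights) - 1) > 1e-8)
    msg <- c(msg, "weights must be non-negative and sum to 1")
  if (length(object@band) != 2 || object@band[1] >= object@band[2])
    msg <- c(msg, "band must be an interval (lower < upper)")
  if (length(msg)) msg else TRUE
})

#' Gaussian mixture model over texture features
#'
#' @slot q number of mixture components.
#' @slot structure covariance structure: "full", "diag", "spherical" or
#'   "tied".
#' @slot means q x D matrix of component means.
#' @slot covariances list of q D x D covariance matrices (shared object
#'   repeated for "tied").
#' @slot weights mixing weights, positive, summing to 1.
#' @slot featureNames the D feature names the model was fitted on.
#' @slot logLik final log-likelihood.
#' @slot logLikTrace per-iteration log-likelihood (monotone
#'   non-decreasing).
#' @slot bic Bayesian Information Criterion (-2 lnL + k ln n).
#' @slot nObs number of training vectors.
#' @slot converged logical.
#' @slot componentLabels substrate label per component (many-to-one
#'   allowed), empty until assigned.
#' @slot seed RNG seed used for initialization.
#' @export
setClass("GmmModel",
  representation(q = "numeric", structure = "character", means = "matrix",
                 covariances = "list", weights = "numeric",
                 featureNames = "character", logLik = "numeric",
                 logLikTrace = "numeric", bic = "numeric", nObs = "numeric",
                 converged = "logical", componentLabels = "character",
                 seed = "numeric"))

setValidity("GmmModel", function(object) {
  msg <- character()
  if (length(object@weights) != object@q ||
      abs(sum(object@weights) - 1) > 1e-6 || any(object@weights <= 0))
    msg <- c(msg, "mixing weights must be positive and sum to 1")
  if (nrow(object@means) != object@q)
    msg <- c(msg, "means must have one row per component")
  if (!object@structure %in% c("full", "diag", "spherical", "tied"))
    msg <- c(msg, "unknown covariance structure")
  if (length(msg)) msg else TRUE
})

#' Per-window substrate classification map
#'
#' @slot windows data.frame with lattice address, centroid coordinates,
#'   predicted label ("sand"/"gravel"/"boulders"/"null"/"other"/"nodata"),
#'   confidence, optional per-class u/alpha or posterior columns, and an
#'   optional downstream distance (m).
#' @slot classes the substrate vocabulary (excluding null/other/nodata).
#' @slot method "lsq" or "gmm".
#' @export
setClass("ClassificationMap",
  representation(windows = "data.frame", classes = "character",
                 method = "character"))

#' SLIC superpixel segmentation
#'
#' @slot labels integer matrix aligned to the raster; NA over nodata,
#'   otherwise a superpixel id in 1..K.
#' @slot nRequested requested superpixel count.
#' @slot compactness SLIC compactness (intensity units per spacing).
#' @slot cellSize raster cell size (m).
#' @slot seed RNG seed.
#' @export
setClass("SuperpixelSegmentation",
  representation(labels = "matrix", nRequested = "numeric",
                 compactness = "numeric", cellSize = "numeric",
                 seed = "numeric"))

## ---- show methods ----

setMethod("show", "IntensityRaster", function(object) {
  cat("IntensityRaster:", nrow(object@values), "x", ncol(object@values),
      "cells @", object@cellSize, "m\n")
  cat("  valid cells:", sum(object@validMask), "/",
      length(object@validMask), "\n")
  cat("  origin (NW): (", object@origin[1], ",", object@origin[2], ")",
      if (nzchar(object@crsTag)) paste0("  crs: ", object@crsTag), "\n")
})

setMethod("show", "SubstratePolygonSet", function(object) {
  cat("SubstratePolygonSet:", length(object@polygons), "polygons\n")
  print(table(label = object@labels, role = object@roles))
})

setMethod("show", "GlcmParams", function(object) {
  cat(sprintf("GlcmParams: d=%d  theta=%d deg  L=%g m  N=%d  %s  coverage>=%g\n",
              as.integer(object@d), as.integer(object@theta), object@L,
              as.integer(object@N),
              if (object@symmetric) "symmetric" else "directed",
              object@coverageMin))
})

setMethod("show", "TextureGrid", function(object) {
  ok <- sum(!is.na(object@windows$E))
  cat("TextureGrid:", nrow(object@windows), "windows (",
      object@windowPx, "px =", object@windowPx * object@cellSize,
      "m );", ok, "with defined features\n")
  show(object@params)
})

setMethod("show", "CalibrationMatrix", function(object) {
  cat("CalibrationMatrix (bootstrap medians, B =", object@B, "):\n")
  print(round(object@C, 4))
})

setMethod("show", "LsqModel", function(object) {
  cat("LsqModel: classes", paste(object@calibration@classNames, collapse = ", "),
      "\n  weights:", paste(format(object@weights), collapse = " "),
      "\n  indeterminate band: (", object@band[1], ",", object@band[2], ")\n")
})

setMethod("show", "GmmModel", function(object) {
  cat(sprintf("GmmModel: q=%d  structure=%s  features=%s\n",
              as.integer(object@q), object@structure,
              paste(object@featureNames, collapse = ",")))
  cat(sprintf("  logLik=%.3f  BIC=%.3f  iterations=%d  converged=%s\n",
              object@logLik, object@bic, length(object@logLikTrace),
              object@converged))
  if (length(object@componentLabels))
    cat("  component labels:", paste(object@componentLabels, collapse = ", "), "\n")
})

setMethod("show", "ClassificationMap", function(object) {
  cat("ClassificationMap (", object@method, "):", nrow(object@windows),
      "windows\n")
  print(table(object@windows$label))
})

setMethod("show", "SuperpixelSegmentation", function(object) {
  k <- length(unique(stats::na.omit(as.vector(object@labels))))
  cat("SuperpixelSegmentation:", k, "superpixels (requested",
      object@nRequested, "), compactness", object@compactness, "\n")
})
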