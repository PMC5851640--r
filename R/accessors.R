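## Constructors and accessors. Slots are never reached into from user code.

#' Create an IntensityRaster
#'
#' @param values numeric matrix of 8-bit grey levels (row 1 =
#'   northernmost).
#' @param validMask logical matrix; defaults to `!is.na(values)`.
#' @param cellSize cell edge length in metres.
#' @param origin (easting, northing) of the north-west grid corner;
#'   defaults to (0, nrow * cellSize) so cell centres have positive
#'   coordinates.
#' @param crsTag opaque CRS string, passed through.
#' @return an [IntensityRaster-class].
#' @export
IntensityRaster <- function(values, validMask = NULL, cellSize = 0.25,
                            origin = NULL, crsTag = "") {
  values <- as.matrix(values)
  if (is.null(validMask)) validMask <- !is.na(values)
  validMask <- as.matrix(validMask)
  storage.mode(validMask) <- "logical"
  values[!validMask] <- NA_real_
  if (is.null(origin)) origin <- c(0, nrow(values) * cellSize)
  new("IntensityRaster", values = values, validMask = validMask,
      cellSize = cellSize, origin = as.numeric(origin), crsTag = crsTag)
}

#' @rdname IntensityRaster
#' @param x an IntensityRaster.
#' @export
rasterValues <- function(x) x@values

#' @rdname IntensityRaster
#' @export
rasterMask <- function(x) x@validMask

#' @rdname IntensityRaster
#' @export
cellSize <- function(x) x@cellSize

#' @rdname IntensityRaster
#' @export
rasterOrigin <- function(x) x@origin

#' @rdname IntensityRaster
#' @export
crsTag <- function(x) x@crsTag

#' Cell-centre coordinates of a raster
#'
#' @param x an [IntensityRaster-class].
#' @param rows,cols 1-based cell addresses (vectorised).
#' @return two-column matrix (easting, northing) of cell centres.
#' @export
cellCenters <- function(x, rows, cols) {
  cbind(easting  = x@origin[1] + (cols - 0.5) * x@cellSize,
        northing = x@origin[2] - (rows - 0.5) * x@cellSize)
}

#' Create a SubstratePolygonSet
#'
#' @param polygons list of n x 2 coordinate matrices (easting, northing).
#'   Open rings are closed automatically.
#' @param labels class label per polygon (exclusion polygons may use
#'   "exclusion").
#' @param roles "calibration", "validation" or "exclusion" per polygon.
#' @param vocabulary declared class vocabulary ordered by grain size.
#' @return a [SubstratePolygonSet-class].
#' @export
SubstratePolygonSet <- function(polygons, labels, roles,
                                vocabulary = c("sand", "gravel", "boulders")) {
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (any(p[1, ] != p[nrow(p), ])) p <- rbind(p, p[1, ])
    unname(p)
  })
  new("SubstratePolygonSet", polygons = polygons,
      labels = as.character(labels), roles = as.character(roles),
      vocabulary = vocabulary)
}

#' @rdname SubstratePolygonSet
#' @param x a SubstratePolygonSet.
#' @export
polygonLabels <- function(x) x@labels

#' @rdname SubstratePolygonSet
#' @export
polygonRoles <- function(x) x@roles

#' @rdname SubstratePolygonSet
#' @export
polygonRings <- function(x) x@polygons

#' @rdname SubstratePolygonSet
#' @export
classVocabulary <- function(x) x@vocabulary

#' Create GLCM parameters
#'
#' @param d search distance in pixels.
#' @param theta reference angle (degrees): 0, 45, 90 or 135.
#' @param L window width in metres.
#' @param N grey levels after quantization.
#' @param symmetric add transpose pairs (default FALSE).
#' @param coverageMin minimum valid-cell fraction per window.
#' @return a [GlcmParams-class].
#' @export
GlcmParams <- function(d = 5, theta = 0, L = 3, N = 64, symmetric = FALSE,
                       coverageMin = 0.75) {
  new("GlcmParams", d = d, theta = theta, L = L, N = N,
      symmetric = symmetric, coverageMin = coverageMin)
}

#' Windows table of a TextureGrid or ClassificationMap
#'
#' @param x a [TextureGrid-class] or [ClassificationMap-class].
#' @return the per-window data.frame.
#' @export
windowsTable <- function(x) x@windows

#' @rdname CalibrationMatrix-class
#' @param x a CalibrationMatrix.
#' @aliases calibrationValues
#' @export
calibrationValues <- function(x) x@C

#' @rdname CalibrationMatrix-class
#' @export
calibrationClasses <- function(x) x@classNames

#' @rdname CalibrationMatrix-class
#' @export
calibrationFeatures <- function(x) x@featureNames

#' Create an LSQ unmixing model
#'
#' @param calibration a [CalibrationMatrix-class].
#' @param weights per-class weights (default equal), normalised to sum
#'   to 1.
#' @param band open indeterminate interval on the confidence alpha.
#' @return an [LsqModel-class].
#' @export
LsqModel <- function(calibration, weights = NULL, band = c(0.15, 0.25)) {
  k <- length(calibration@classNames)
  if (is.null(weights)) weights <- rep(1 / k, k)
  weights <- weights / sum(weights)
  names(weights) <- calibration@classNames
  new("LsqModel", calibration = calibration, weights = weights,
      band = as.numeric(band))
}

#' @rdname LsqModel
#' @param x an LsqModel.
#' @export
modelWeights <- function(x) x@weights

#' @rdname GmmModel-class
#' @param x a GmmModel.
#' @aliases componentMeans
#' @export
componentMeans <- function(x) x@means

#' @rdname GmmModel-class
#' @export
componentLabels <- function(x) x@componentLabels

#' @rdname GmmModel-class
#' @export
mixingWeights <- function(x) x@weights

#' @rdname GmmModel-class
#' @export
logLikTrace <- function(x) x@logLikTrace

#' @rdname GmmModel-class
#' @export
modelBic <- function(x) x@bic

#' @rdname SuperpixelSegmentation-class
#' @param x a SuperpixelSegmentation.
#' @aliases superpixelLabels
#' @export
superpixelLabels <- function(x) x@labels

#' Per-superpixel areas
#'
#' @param x a [SuperpixelSegmentation-class].
#' @return named numeric vector of areas in square metres.
#' @export
superpixelAreas <- function(x) {
  tab <- table(x@labels)
  setNames(as.numeric(tab) * x@cellSize^2, names(tab))
}
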