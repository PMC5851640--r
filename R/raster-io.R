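## Raster / polygon / point-cloud I/O and gridding.

#' Resample a sonar intensity point cloud onto a regular grid
#'
#' Grids (easting, northing, intensity) points at `cellSize` resolution.
#' Three resampling methods are available: `nearest` (value of the
#' nearest point within `searchRadius`, ties broken by lowest point
#' index), `idw` (inverse-distance-weighted mean of points in radius) and
#' `gaussian` (Gaussian-kernel-weighted mean, bandwidth
#' `searchRadius / 2`). Grid nodes with no point within the radius are
#' nodata.
#'
#' @param cloud data.frame with columns easting, northing, intensity.
#' @param cellSize grid cell size in metres (default 0.25).
#' @param method "nearest", "idw" or "gaussian".
#' @param searchRadius neighbourhood radius in metres (default
#'   `2 * cellSize`).
#' @param extent optional c(xmin, xmax, ymin, ymax); defaults to the point
#'   bounding box snapped outward to the cell lattice.
#' @param crsTag CRS string to attach.
#' @return an [IntensityRaster-class].
#' @export
gridPointCloud <- function(cloud, cellSize = 0.25,
                           method = c("nearest", "idw", "gaussian"),
                           searchRadius = 2 * cellSize, extent = NULL,
                           crsTag = "") {
  method <- match.arg(method)
  cloud <- as.data.frame(cloud)
  if (nrow(cloud) < 1) stop("point cloud is empty")
  xy <- cbind(cloud$easting, cloud$northing)
  if (any(!is.finite(xy))) stop("point cloud has non-finite coordinates")
  if (cellSize <= 0) stop("cellSize must be positive")
  if (searchRadius <= 0) stop("searchRadius must be positive")
  z <- cloud$intensity

  if (is.null(extent)) {
    extent <- c(floor(min(xy[, 1]) / cellSize) * cellSize,
                ceiling(max(xy[, 1]) / cellSize) * cellSize,
                floor(min(xy[, 2]) / cellSize) * cellSize,
                ceiling(max(xy[, 2]) / cellSize) * cellSize)
    # degenerate extents (single point on a lattice line) get one cell
    if (extent[2] <= extent[1]) extent[2] <- extent[1] + cellSize
    if (extent[4] <= extent[3]) extent[4] <- extent[3] + cellSize
  }
  nc <- max(1L, round((extent[2] - extent[1]) / cellSize))
  nr <- max(1L, round((extent[4] - extent[3]) / cellSize))
  origin <- c(extent[1], extent[4])

  # bucket points by cell for local neighbourhood search
  pc <- pmin(pmax(floor((xy[, 1] - origin[1]) / cellSize), 0), nc - 1)
  pr <- pmin(pmax(floor((origin[2] - xy[, 2]) / cellSize), 0), nr - 1)
  buckets <- split(seq_len(nrow(xy)), pr * nc + pc)
  ring <- ceiling(searchRadius / cellSize)

  vals <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    rows <- max(1, r - ring):min(nr, r + ring)
    cy <- origin[2] - (r - 0.5) * cellSize
    for (cc in seq_len(nc)) {
      cols <- max(1, cc - ring):min(nc, cc + ring)
      keys <- as.character(outer((rows - 1) * nc, cols - 1, "+"))
      cand <- unlist(buckets[keys], use.names = FALSE)
      if (!length(cand)) next
      cx <- origin[1] + (cc - 0.5) * cellSize
      d2 <- (xy[cand, 1] - cx)^2 + (xy[cand, 2] - cy)^2
      keep <- d2 <= searchRadius^2
      if (!any(keep)) next
      cand <- cand[keep]; d2 <- d2[keep]
      vals[r, cc] <- switch(method,
        nearest = {
          # ties broken by lowest point index: cand is in increasing
          # index order within buckets, so order() on d2 alone suffices
          o <- order(d2, cand)
          z[cand[o[1]]]
        },
        idw = {
          w <- 1 / pmax(sqrt(d2), 1e-12)
          sum(w * z[cand]) / sum(w)
        },
        gaussian = {
          w <- exp(-d2 / (2 * (searchRadius / 2)^2))
          sum(w * z[cand]) / sum(w)
        })
    }
  }
  IntensityRaster(vals, cellSize = cellSize, origin = origin,
                  crsTag = crsTag)
}

## ---- ESRI ASCII grid ----

#' Read / write rasters
#'
#' `writeRaster`/`readRaster` dispatch on the file extension: `.asc`
#' (ESRI ASCII grid, the canonical lossless text format; the CRS tag and
#' the valid mask travel in a `.prj` sidecar and the NODATA value) or
#' `.tif` (8-bit TIFF written with a second mask sample, plus `.tfw`
#' world file and `.prj` sidecar). Round-trips preserve values, mask,
#' cell size, origin and CRS tag exactly.
#'
#' @param raster an [IntensityRaster-class].
#' @param path file path ending in `.asc` or `.tif`.
#' @return `readRaster` returns an [IntensityRaster-class];
#'   `writeRaster` returns `path` invisibly.
#' @export
writeRaster <- function(raster, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    asc = writeRasterAsc(raster, path),
    tif = ,
    tiff = writeRasterTif(raster, path),
    stop("unsupported raster format: .", ext))
  invisible(path)
}

#' @rdname writeRaster
#' @export
readRaster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    asc = readRasterAsc(path),
    tif = ,
    tiff = readRasterTif(path),
    stop("unsupported raster format: .", ext))
}

prjPath <- function(path) paste0(tools::file_path_sans_ext(path), ".prj")

writeRasterAsc <- function(raster, path) {
  v <- raster@values
  v[!raster@validMask] <- -9999
  hdr <- c(paste("ncols", ncol(v)),
           paste("nrows", nrow(v)),
           paste("xllcorner", format(raster@origin[1], digits = 15)),
           paste("yllcorner",
                 format(raster@origin[2] - nrow(v) * raster@cellSize,
                        digits = 15)),
           paste("cellsize", format(raster@cellSize, digits = 15)),
           "NODATA_value -9999")
  body <- apply(v, 1, function(row) paste(format(row, digits = 15,
                                                 trim = TRUE),
                                          collapse = " "))
  writeLines(c(hdr, body), path)
  if (nzchar(raster@crsTag)) writeLines(raster@crsTag, prjPath(path))
  invisible(path)
}

readRasterAsc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  nod <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc) stop("malformed ASCII grid: ", path)
  m <- matrix(vals, nr, nc, byrow = TRUE)
  mask <- m != nod
  m[!mask] <- NA_real_
  crs <- if (file.exists(prjPath(path))) {
    paste(readLines(prjPath(path)), collapse = "\n")
  } else ""
  IntensityRaster(m, mask, cellSize = hdr$cellsize,
                  origin = c(hdr$xllcorner,
                             hdr$yllcorner + nr * hdr$cellsize),
                  crsTag = crs)
}

## ---- TIFF + world file ----

writeRasterTif <- function(raster, path) {
  v <- raster@values / 255
  v[!raster@validMask] <- 0
  arr <- array(0, dim = c(nrow(v), ncol(v), 2))
  arr[, , 1] <- v
  arr[, , 2] <- raster@validMask * 1
  tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  # world file: pixel size and centre of the upper-left cell
  tfw <- c(raster@cellSize, 0, 0, -raster@cellSize,
           raster@origin[1] + raster@cellSize / 2,
           raster@origin[2] - raster@cellSize / 2)
  writeLines(format(tfw, digits = 15), paste0(tools::file_path_sans_ext(path), ".tfw"))
  if (nzchar(raster@crsTag)) writeLines(raster@crsTag, prjPath(path))
  invisible(path)
}

readRasterTif <- function(path) {
  # the second sample is a validity mask, not a color channel; libtiff
  # warns about the unusual layout, harmlessly
  arr <- suppressWarnings(tiff::readTIFF(path))
  if (length(dim(arr)) != 3 || dim(arr)[3] < 2)
    stop("not a mask-carrying raster TIFF: ", path)
  tfwPath <- paste0(tools::file_path_sans_ext(path), ".tfw")
  if (!file.exists(tfwPath)) stop("missing world file for ", path)
  tfw <- as.numeric(readLines(tfwPath))
  cellSize <- tfw[1]
  mask <- arr[, , 2] > 0.5
  vals <- round(arr[, , 1] * 255)
  vals[!mask] <- NA_real_
  crs <- if (file.exists(prjPath(path))) {
    paste(readLines(prjPath(path)), collapse = "\n")
  } else ""
  IntensityRaster(vals, mask, cellSize = cellSize,
                  origin = c(tfw[5] - cellSize / 2, tfw[6] + cellSize / 2),
                  crsTag = crs)
}

## ---- GeoJSON polygons ----

#' Read / write substrate polygons as GeoJSON
#'
#' A minimal GeoJSON FeatureCollection interface: Polygon features (outer
#' ring only) with properties `class` and `role`.
#'
#' @param path GeoJSON file path.
#' @param vocabulary class vocabulary for validation, ordered by grain
#'   size.
#' @param polys a [SubstratePolygonSet-class].
#' @return `readPolygons` returns a [SubstratePolygonSet-class].
#' @export
readPolygons <- function(path, vocabulary = c("sand", "gravel", "boulders")) {
  if (!file.exists(path)) stop("file not found: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  rings <- list(); labels <- character(); roles <- character()
  for (f in gj$features) {
    if (!identical(f$geometry$type, "Polygon")) next
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(pt) as.numeric(pt[1:2])))
    rings[[length(rings) + 1L]] <- ring
    labels <- c(labels, as.character(f$properties$class))
    role <- f$properties$role
    roles <- c(roles, if (is.null(role)) "calibration" else as.character(role))
  }
  bad <- setdiff(labels, c(vocabulary, "exclusion"))
  if (length(bad))
    stop("unknown class label(s) in ", path, ": ", paste(bad, collapse = ", "))
  SubstratePolygonSet(rings, labels, roles, vocabulary)
}

#' @rdname readPolygons
#' @export
writePolygons <- function(polys, path) {
  feats <- lapply(seq_along(polys@polygons), function(i) {
    ring <- polys@polygons[[i]]
    list(type = "Feature",
         properties = list(class = polys@labels[i], role = polys@roles[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(j) ring[j, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## ---- rasterization ----

# point-in-polygon on cell centres; mgcv::in.out treats the ring as closed
pointsInRing <- function(ring, pts) {
  inside <- rep(FALSE, nrow(pts))
  bb <- apply(ring, 2, range)
  cand <- pts[, 1] >= bb[1, 1] & pts[, 1] <= bb[2, 1] &
          pts[, 2] >= bb[1, 2] & pts[, 2] <= bb[2, 2]
  if (any(cand))
    inside[cand] <- mgcv::in.out(ring, pts[cand, , drop = FALSE])
  inside
}

#' Rasterize substrate polygons onto a raster's cell lattice
#'
#' Each cell is assigned by cell-centre containment. Overlapping polygons
#' are resolved deterministically: later-listed polygons win. Exclusion
#' polygons remove cells from the raster's valid mask instead of
#' labelling them.
#'
#' @param polys a [SubstratePolygonSet-class] in the raster CRS.
#' @param raster an [IntensityRaster-class].
#' @param roles which polygon roles to rasterize as labels (exclusions
#'   are always applied).
#' @return list with `labels` (character matrix, NA where unlabelled) and
#'   `raster` (input raster with exclusion cells masked out).
#' @export
rasterizePolygons <- function(polys, raster,
                              roles = c("calibration", "validation")) {
  nr <- nrow(raster@values); nc <- ncol(raster@values)
  ctr <- cellCenters(raster, rep(seq_len(nr), nc),
                     rep(seq_len(nc), each = nr))
  labels <- matrix(NA_character_, nr, nc)
  mask <- raster@validMask
  for (i in seq_along(polys@polygons)) {
    inside <- pointsInRing(polys@polygons[[i]], ctr)
    if (polys@roles[i] == "exclusion") {
      mask[matrix(inside, nr, nc)] <- FALSE
    } else if (polys@roles[i] %in% roles) {
      labels[matrix(inside, nr, nc)] <- polys@labels[i]
    }
  }
  labels[!mask] <- NA_character_
  out <- raster
  out@validMask <- mask
  out@values[!mask] <- NA_real_
  list(labels = labels, raster = out)
}
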