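## Seeded synthetic echogram generator. Emulates the *statistical* texture
## structure the classifiers assume - smooth ordered fields for sand,
## fine speckle for gravel, sparse bright clasts with acoustic shadows
## for boulders - not sonar physics.

#' Texture specification for one substrate class
#'
#' @param name class name.
#' @param corLength correlation length of the random field, in cells
#'   (Gaussian smoothing scale).
#' @param contrast grey-level standard deviation of the field.
#' @param baseLevel mean grey level.
#' @param blobDensity expected supra-pixel clasts per cell (0 for none).
#' @param blobRadius clast radius in cells.
#' @param blobHeight grey-level boost at a clast.
#' @param shadowProb probability a clast casts an adjacent dark shadow.
#' @param shadowDepth grey-level drop in the shadow.
#' @return a list of class "textureClassSpec".
#' @export
textureClassSpec <- function(name, corLength, contrast, baseLevel,
                             blobDensity = 0, blobRadius = 0,
                             blobHeight = 0, shadowProb = 0,
                             shadowDepth = 0) {
  stopifnot(corLength >= 0, contrast >= 0, blobDensity >= 0,
            blobRadius >= 0, shadowProb >= 0, shadowProb <= 1)
  structure(list(name = name, corLength = corLength, contrast = contrast,
                 baseLevel = baseLevel, blobDensity = blobDensity,
                 blobRadius = blobRadius, blobHeight = blobHeight,
                 shadowProb = shadowProb, shadowDepth = shadowDepth),
            class = "textureClassSpec")
}

#' Default substrate texture specifications
#'
#' Sand: long-correlation, low-contrast field (ordered, smooth). Gravel:
#' a patchy continuum of two speckle sub-textures - fine gravel near the
#' sub-pixel scale (textures bordering sand's) and coarse gravel with
#' occasional small clasts (bordering boulders') - reflecting that
#' gravelly beds span the whole intermixed sand-to-cobble spectrum.
#' Boulders: moderate field plus dense supra-pixel bright clasts, each
#' usually paired with a dark acoustic shadow, giving high-contrast
#' disordered texture.
#'
#' A class entry may be a single [textureClassSpec()] or an (unnamed)
#' list of sub-specs; sub-specs are rendered as alternating down-range
#' patches within the class's region.
#'
#' @return named list of class texture specifications.
#' @export
defaultClassSpecs <- function() {
  list(
    sand = textureClassSpec("sand", corLength = 6, contrast = 10,
                            baseLevel = 120),
    gravel = list(
      textureClassSpec("gravel_fine", corLength = 2, contrast = 16,
                       baseLevel = 126),
      textureClassSpec("gravel_coarse", corLength = 1, contrast = 26,
                       baseLevel = 132, blobDensity = 0.015,
                       blobRadius = 1.2, blobHeight = 55,
                       shadowProb = 0.5, shadowDepth = 45)),
    boulders = textureClassSpec("boulders", corLength = 1.5, contrast = 20,
                                baseLevel = 110, blobDensity = 0.05,
                                blobRadius = 1.5, blobHeight = 85,
                                shadowProb = 0.9, shadowDepth = 75))
}

# separable Gaussian smoothing with reflective padding
gaussSmooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad <- function(x, n) c(rev(x[seq_len(n)]), x, rev(x[length(x) - seq_len(n) + 1]))
  smooth1 <- function(x) {
    stats::filter(pad(x, half), k, sides = 2)[(half + 1):(half + length(x))]
  }
  m <- apply(m, 2, smooth1)
  t(apply(t(m), 2, smooth1))
}

correlatedField <- function(nr, nc, corLength, contrast) {
  f <- matrix(rnorm(nr * nc), nr, nc)
  f <- gaussSmooth(f, corLength)
  s <- sd(as.vector(f))
  if (s > 0) f <- f / s
  f * contrast
}

renderClassTexture <- function(nr, nc, spec) {
  f <- spec$baseLevel + correlatedField(nr, nc, spec$corLength,
                                        spec$contrast)
  if (spec$blobDensity > 0) {
    nBlob <- rpois(1, spec$blobDensity * nr * nc)
    if (nBlob > 0) {
      br <- runif(nBlob, 1, nr)
      bc <- runif(nBlob, 1, nc)
      rad <- pmax(1, spec$blobRadius * runif(nBlob, 0.6, 1.4))
      shadow <- runif(nBlob) < spec$shadowProb
      rows <- matrix(seq_len(nr), nr, nc)
      cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      for (b in seq_len(nBlob)) {
        d2 <- (rows - br[b])^2 + (cols - bc[b])^2
        f[d2 <= rad[b]^2] <- f[d2 <= rad[b]^2] + spec$blobHeight
        if (shadow[b]) {
          # shadow trails the clast down-range (next rows)
          d2s <- (rows - (br[b] + 2 * rad[b]))^2 + (cols - bc[b])^2
          f[d2s <= (1.2 * rad[b])^2] <-
            f[d2s <= (1.2 * rad[b])^2] - spec$shadowDepth
        }
      }
    }
  }
  f
}

#' Default synthetic scene layout
#'
#' A 400 x 120 cell reach (100 m x 30 m at 0.25 m) of three equal
#' downstream bands - sand, gravel, boulders - with an 8-column nadir
#' nodata stripe. Each band carries one calibration and one validation
#' rectangle (disjoint), and the nadir stripe an exclusion polygon.
#'
#' @param nrow,ncol raster shape in cells.
#' @param cellSize cell size in metres.
#' @return list with `nrow`, `ncol`, `cellSize`, `bands` (data.frame
#'   row0/row1/class, 1-based inclusive), `nadirCols`, and `polys`
#'   (a [SubstratePolygonSet-class]).
#' @export
defaultSceneLayout <- function(nrow = 400, ncol = 120, cellSize = 0.25) {
  classes <- c("sand", "gravel", "boulders")
  cuts <- round(seq(0, nrow, length.out = 4))
  bands <- data.frame(row0 = cuts[1:3] + 1, row1 = cuts[2:4],
                      class = classes)
  nadirCols <- seq(floor(ncol / 2) - 3, floor(ncol / 2) + 4)
  originN <- nrow * cellSize
  rect <- function(r0, r1, c0, c1) {
    # cell index range (1-based inclusive) -> coordinate ring
    cbind(c(c0 - 1, c1, c1, c0 - 1, c0 - 1) * cellSize,
          originN - c(r0 - 1, r0 - 1, r1, r1, r0 - 1) * cellSize)
  }
  polys <- list(); labels <- character(); roles <- character()
  for (b in seq_len(nrow(bands))) {
    r0 <- bands$row0[b]; r1 <- bands$row1[b]
    h <- r1 - r0 + 1
    # calibration: upstream 40% of the band; validation: downstream 40%
    polys <- c(polys,
               list(rect(r0 + round(0.05 * h), r0 + round(0.40 * h),
                         6, ncol - 5),
                    rect(r0 + round(0.55 * h), r0 + round(0.90 * h),
                         6, ncol - 5)))
    labels <- c(labels, bands$class[b], bands$class[b])
    roles <- c(roles, "calibration", "validation")
  }
  polys <- c(polys, list(rect(1, nrow, min(nadirCols), max(nadirCols))))
  labels <- c(labels, "exclusion")
  roles <- c(roles, "exclusion")
  list(nrow = nrow, ncol = ncol, cellSize = cellSize, bands = bands,
       nadirCols = nadirCols,
       polys = SubstratePolygonSet(polys, labels, roles, classes))
}

#' Simulate an echogram-like intensity raster
#'
#' Renders each layout band with its class texture specification, masks
#' the nadir stripe, clips to the 8-bit range and rounds to integer grey
#' levels. Bit-reproducible given `seed`.
#'
#' @param layout a scene layout (see [defaultSceneLayout()]).
#' @param specs named list of [textureClassSpec()] per class (default
#'   [defaultClassSpecs()]).
#' @param seed RNG seed.
#' @return list with `raster` (an [IntensityRaster-class]), `polys`
#'   (the layout's labelled polygons) and `truth` (character matrix of
#'   planted classes per cell).
#' @export
simulateEchogram <- function(layout = defaultSceneLayout(),
                             specs = defaultClassSpecs(), seed = 1) {
  missing <- setdiff(layout$bands$class, names(specs))
  if (length(missing))
    stop("no texture spec for class(es): ", paste(missing, collapse = ", "))
  set.seed(seed)
  nr <- layout$nrow; nc <- layout$ncol
  v <- matrix(NA_real_, nr, nc)
  truth <- matrix(NA_character_, nr, nc)
  for (b in seq_len(nrow(layout$bands))) {
    rows <- layout$bands$row0[b]:layout$bands$row1[b]
    cls <- layout$bands$class[b]
    spec <- specs[[cls]]
    if (inherits(spec, "textureClassSpec")) {
      v[rows, ] <- renderClassTexture(length(rows), nc, spec)
    } else {
      # sub-texture continuum: alternating down-range patches of the
      # sub-specs (patch height about two window widths)
      nChunk <- max(length(spec), round(length(rows) / 24))
      cuts <- round(seq(0, length(rows), length.out = nChunk + 1))
      which <- rep(seq_along(spec), length.out = nChunk)
      for (ch in seq_len(nChunk)) {
        sub <- rows[(cuts[ch] + 1):cuts[ch + 1]]
        v[sub, ] <- renderClassTexture(length(sub), nc, spec[[which[ch]]])
      }
    }
    truth[rows, ] <- cls
  }
  mask <- matrix(TRUE, nr, nc)
  if (length(layout$nadirCols)) mask[, layout$nadirCols] <- FALSE
  v <- round(pmin(pmax(v, 0), 255))
  v[!mask] <- NA_real_
  list(raster = IntensityRaster(v, mask, cellSize = layout$cellSize,
                                origin = c(0, nr * layout$cellSize),
                                crsTag = "synthetic-local"),
       polys = layout$polys, truth = truth)
}

#' Sample labelled vectors from a Gaussian mixture
#'
#' @param components list of lists with `mean`, `cov` (matrix) and
#'   `weight`; weights must sum to 1 and covariances be positive
#'   definite.
#' @param n number of draws.
#' @param seed RNG seed.
#' @return list with `V` (n x D matrix) and `labels` (true component
#'   index per row).
#' @export
simulateFeatureMixture <- function(components, n, seed = 1) {
  w <- vapply(components, function(cp) cp$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-8) stop("component weights must sum to 1")
  for (cp in components) {
    ev <- eigen(as.matrix(cp$cov), symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) stop("covariance is not positive definite")
  }
  set.seed(seed)
  labels <- sample.int(length(components), n, replace = TRUE, prob = w)
  D <- length(components[[1]]$mean)
  V <- matrix(NA_real_, n, D)
  for (k in seq_along(components)) {
    idx <- which(labels == k)
    if (length(idx))
      V[idx, ] <- MASS::mvrnorm(length(idx), components[[k]]$mean,
                                as.matrix(components[[k]]$cov))
  }
  list(V = V, labels = labels)
}

#' Scatter a point cloud from a raster
#'
#' Emits `density` points per valid cell, jittered uniformly within
#' `jitter` cell widths of the cell centre, each carrying the cell's
#' intensity. With `density = 1, jitter = 0`, nearest-neighbour gridding
#' recovers the raster exactly.
#'
#' @param raster an [IntensityRaster-class].
#' @param density points per valid cell (fractional part realised by
#'   Bernoulli thinning).
#' @param jitter positional jitter in cell widths (0..0.5 keeps points
#'   inside their cell).
#' @param seed RNG seed.
#' @return data.frame with columns easting, northing, intensity.
#' @export
simulatePointCloud <- function(raster, density = 1, jitter = 0, seed = 1) {
  if (density <= 0) stop("density must be positive")
  set.seed(seed)
  idx <- which(raster@validMask, arr.ind = TRUE)
  base <- floor(density)
  reps <- rep(base, nrow(idx)) +
    (runif(nrow(idx)) < (density - base))
  idx <- idx[rep(seq_len(nrow(idx)), reps), , drop = FALSE]
  if (!nrow(idx)) stop("density too low: no points emitted")
  ctr <- cellCenters(raster, idx[, 1], idx[, 2])
  cs <- raster@cellSize
  data.frame(
    easting = ctr[, 1] + runif(nrow(idx), -jitter, jitter) * cs,
    northing = ctr[, 2] + runif(nrow(idx), -jitter, jitter) * cs,
    intensity = raster@values[idx])
}
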