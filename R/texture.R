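## GLCM texture features on a non-overlapping window lattice.

# offset convention: theta=0 -> (drow, dcol) = (0, +d); 45 -> (-d, +d);
# 90 -> (-d, 0); 135 -> (-d, -d)
glcmOffset <- function(d, theta) {
  switch(as.character(theta),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("theta must be 0, 45, 90 or 135"))
}

#' Quantize an 8-bit raster to N grey levels
#'
#' Fixed global scaling `floor(g * N / 256)` from the 8-bit domain (not
#' per-image min-max), so signatures calibrated on one scan transfer to
#' another. The mask is unchanged.
#'
#' @param raster an [IntensityRaster-class] with values in \[0, 255\].
#' @param N number of grey levels (>= 2).
#' @return an [IntensityRaster-class] whose values are quantized levels
#'   0..N-1.
#' @export
quantizeRaster <- function(raster, N) {
  if (N < 2) stop("N must be >= 2")
  v <- raster@values[raster@validMask]
  if (length(v) && (any(v < 0) || any(v > 255)))
    stop("values outside the 8-bit domain [0, 255]")
  out <- raster
  out@values <- floor(raster@values * N / 256)
  out@values[!raster@validMask] <- NA_real_
  out
}

# extract directed level pairs (i, j) for one offset from a level matrix
# with NAs at invalid cells
glcmPairsIJ <- function(W, dr, dc) {
  nr <- nrow(W); nc <- ncol(W)
  r1 <- max(1, 1 - dr); r2 <- min(nr, nr - dr)
  c1 <- max(1, 1 - dc); c2 <- min(nc, nc - dc)
  if (r1 > r2 || c1 > c2) return(cbind(i = numeric(0), j = numeric(0)))
  i <- W[r1:r2, c1:c2]
  j <- W[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc)]
  ok <- !is.na(i) & !is.na(j)
  cbind(i = i[ok], j = j[ok])
}

#' Compute a grey-level co-occurrence matrix for one window
#'
#' Tabulates directed pairs (reference level i, level j at offset
#' (d, theta)); both pixels must be valid for a pair to count. With
#' `symmetric = TRUE` the transpose pairs are added. The matrix is
#' normalised to probabilities, `P(i, j) = V(i, j) / sum(V)`.
#'
#' @param window integer matrix of quantized levels 0..N-1, NA at invalid
#'   cells (a mask may alternatively be supplied via `mask`).
#' @param params a [GlcmParams-class] (d, theta, N, symmetric used).
#' @param mask optional logical matrix; FALSE cells are treated invalid.
#' @return list with `P` (N x N probability matrix, reference level i in
#'   rows), `V` (raw counts) and `nPairs`; `nPairs = 0` signals an
#'   undefined GLCM (window skipped upstream).
#' @export
computeGlcm <- function(window, params, mask = NULL) {
  W <- as.matrix(window)
  if (!is.null(mask)) W[!mask] <- NA
  N <- as.integer(params@N)
  off <- glcmOffset(as.integer(params@d), params@theta)
  ij <- glcmPairsIJ(W, off[1], off[2])
  if (params@symmetric && nrow(ij)) ij <- rbind(ij, ij[, 2:1, drop = FALSE])
  if (!nrow(ij))
    return(list(P = matrix(0, N, N), V = matrix(0, N, N), nPairs = 0L))
  counts <- tabulate(ij[, 1] * N + ij[, 2] + 1, nbins = N * N)
  V <- matrix(counts, N, N, byrow = TRUE)  # rows = reference level i
  list(P = V / sum(V), V = V, nPairs = sum(V))
}

#' Scalar texture metrics of a GLCM
#'
#' Computes homogeneity `H = sum P(i,j) / (1 + (i-j)^2)`, entropy
#' `E = -sum P ln P` (0 ln 0 = 0, natural log), GLCM mean
#' `mu = sum i P(i,j)`, GLCM variance `sum (i-mu)^2 P(i,j)` (moments of
#' the reference-level marginal), the contrast-reversed `Hprime = 1 - H`,
#' and the co-occurrence correlation of the i and j marginals
#' (`corrG = sum (i-mu_i)(j-mu_j) P / (sigma_i sigma_j)`, NA when either
#' marginal variance is zero).
#'
#' @param glcm result of [computeGlcm()] (or any list with a normalised
#'   `P`).
#' @return named numeric vector: E, H, Hprime, muG, varG, corrG.
#' @export
glcmFeatures <- function(glcm) {
  P <- glcm$P
  if (abs(sum(P) - 1) > 1e-8) stop("GLCM is not normalised")
  N <- nrow(P)
  lev <- seq_len(N) - 1
  I <- matrix(lev, N, N)            # reference level i, constant in rows
  J <- t(I)
  H <- sum(P / (1 + (I - J)^2))
  nz <- P > 0
  E <- -sum(P[nz] * log(P[nz]))
  muI <- sum(I * P)
  varI <- sum((I - muI)^2 * P)
  muJ <- sum(J * P)
  varJ <- sum((J - muJ)^2 * P)
  corrG <- if (varI > 0 && varJ > 0) {
    sum((I - muI) * (J - muJ) * P) / sqrt(varI * varJ)
  } else NA_real_
  c(E = E, H = H, Hprime = 1 - H, muG = muI, varG = varI, corrG = corrG)
}

#' Texture features over a non-overlapping window lattice
#'
#' Quantizes the raster to `N` levels and tiles it into non-overlapping
#' `L x L` windows anchored at the raster origin (only whole windows are
#' tiled: the lattice is `floor(rows/L_px) x floor(cols/L_px)`). A
#' window's features are defined only when at least `coverageMin` of its
#' `L_px^2` cells are valid and at least one pixel pair is countable.
#'
#' @param raster an [IntensityRaster-class].
#' @param params a [GlcmParams-class].
#' @return a [TextureGrid-class].
#' @export
slidingTextureGrid <- function(raster, params) {
  Lpx <- round(params@L / raster@cellSize)
  if (Lpx <= params@d)
    stop("window width (", Lpx, " px) must exceed search distance d = ",
         params@d)
  q <- quantizeRaster(raster, params@N)
  lev <- q@values
  nr <- nrow(lev) %/% Lpx
  nc <- ncol(lev) %/% Lpx
  if (nr < 1 || nc < 1) stop("raster smaller than one window")
  rows <- vector("list", nr * nc)
  k <- 0
  for (wr in seq_len(nr)) {
    for (wc in seq_len(nc)) {
      r0 <- (wr - 1) * Lpx; c0 <- (wc - 1) * Lpx
      W <- lev[r0 + seq_len(Lpx), c0 + seq_len(Lpx), drop = FALSE]
      coverage <- mean(!is.na(W))
      feats <- c(E = NA_real_, H = NA_real_, Hprime = NA_real_,
                 muG = NA_real_, varG = NA_real_, corrG = NA_real_)
      if (coverage >= params@coverageMin) {
        g <- computeGlcm(W, params)
        if (g$nPairs > 0) feats <- glcmFeatures(g)
      }
      ctr <- c(raster@origin[1] + (c0 + Lpx / 2) * raster@cellSize,
               raster@origin[2] - (r0 + Lpx / 2) * raster@cellSize)
      k <- k + 1
      rows[[k]] <- data.frame(wrow = wr - 1L, wcol = wc - 1L,
                              row0 = r0, col0 = c0,
                              easting = ctr[1], northing = ctr[2],
                              coverage = coverage, t(feats))
    }
  }
  new("TextureGrid", windows = do.call(rbind, rows), params = params,
      windowPx = Lpx, cellSize = raster@cellSize, origin = raster@origin)
}

#' Sweep GLCM parameters over a raster
#'
#' One [TextureGrid-class] per combination of search distance, reference
#' angle and window width (the full parameter key is recorded), as used
#' to screen which texture features discriminate substrates.
#'
#' @param raster an [IntensityRaster-class].
#' @param dSet,thetaSet,LSet parameter sets (non-empty).
#' @param metricSet which scalar metrics the sweep targets (recorded;
#'   all six are computed per grid).
#' @param N,symmetric,coverageMin shared GLCM settings.
#' @return data.frame with columns d, theta, L, nDefined and a `grid`
#'   list-column of TextureGrids; attribute `metricSet` records the
#'   metric selection, so the sweep spans
#'   `length(dSet) * length(thetaSet) * length(LSet) * length(metricSet)`
#'   texture features.
#' @export
parameterSweep <- function(raster, dSet, thetaSet, LSet,
                           metricSet = c("E", "H", "muG", "varG", "corrG"),
                           N = 64, symmetric = FALSE, coverageMin = 0.75) {
  if (!length(dSet) || !length(thetaSet) || !length(LSet) ||
      !length(metricSet))
    stop("parameter sets must be non-empty")
  combos <- expand.grid(d = dSet, theta = thetaSet, L = LSet,
                        KEEP.OUT.ATTRS = FALSE)
  grids <- vector("list", nrow(combos))
  nDefined <- rep(NA_integer_, nrow(combos))
  err <- character(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    p <- GlcmParams(d = combos$d[i], theta = combos$theta[i],
                    L = combos$L[i], N = N, symmetric = symmetric,
                    coverageMin = coverageMin)
    g <- tryCatch(slidingTextureGrid(raster, p), error = function(e) e)
    if (inherits(g, "error")) {
      # per-combination failure (e.g. window not wider than d) is
      # recorded, not fatal to the sweep
      err[i] <- conditionMessage(g)
      grids[i] <- list(NULL)
    } else {
      grids[[i]] <- g
      nDefined[i] <- sum(!is.na(g@windows$E))
    }
  }
  out <- cbind(combos, nDefined = nDefined, error = err)
  out$grid <- grids
  attr(out, "metricSet") <- metricSet
  out
}

#' Export a texture grid as CSV
#'
#' One row per window: lattice address (0-based), centroid coordinates,
#' coverage and the six metrics.
#'
#' @param tex a [TextureGrid-class].
#' @param path output CSV path.
#' @export
writeTextureCsv <- function(tex, path) {
  write.csv(tex@windows, path, row.names = FALSE)
  invisible(path)
}
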