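## SLIC superpixel windowing: iterative clustering in (intensity, row,
## col) space, the superpixel-count heuristic, and per-superpixel GLCM
## features.

#' Segment a raster into SLIC superpixels
#'
#' Simple Linear Iterative Clustering on valid cells: cluster centres are
#' seeded on a square grid of spacing `S = sqrt(nValid / n)`, snapped to
#' the nearest valid cell, then iteratively refined by assigning each
#' cell within a 2S x 2S search window to the centre minimising the
#' combined distance `sqrt(dI^2 + (compactness * ds / S)^2)` (dI in grey
#' levels, ds in cells) and re-computing centres as member means.
#' Afterwards, disconnected fragments of a superpixel are merged into
#' their dominant neighbouring superpixel, and any valid cell left
#' unassigned joins its nearest centre.
#'
#' @param raster an [IntensityRaster-class].
#' @param n requested superpixel count (>= 1).
#' @param compactness trade-off between intensity similarity and spatial
#'   tightness, in grey-level units per spacing (default 10 on the 8-bit
#'   scale).
#' @param seed RNG seed (centre jitter is deterministic given it).
#' @param iterations refinement iterations (default 10).
#' @return a [SuperpixelSegmentation-class].
#' @export
slicSegment <- function(raster, n, compactness = 10, seed = 1,
                        iterations = 10) {
  v <- raster@values
  mask <- raster@validMask
  nValid <- sum(mask)
  if (n < 1) stop("n must be >= 1")
  if (nValid < 1) stop("raster has no valid cells")
  if (n > nValid) stop("n exceeds the number of valid cells")
  nr <- nrow(v); nc <- ncol(v)
  S <- max(1, sqrt(nValid / n))

  # seed centres on a square lattice, keep those on/near valid cells
  set.seed(seed)
  gr <- seq(S / 2, nr, by = S)
  gc <- seq(S / 2, nc, by = S)
  ctr <- expand.grid(row = gr, col = gc)
  validIdx <- which(mask, arr.ind = TRUE)
  snap <- function(r, cc) {
    d2 <- (validIdx[, 1] - r)^2 + (validIdx[, 2] - cc)^2
    validIdx[which.min(d2), ]
  }
  centres <- t(apply(ctr, 1, function(x) snap(x[1], x[2])))
  centres <- unique(centres)
  # trim or pad to exactly n centres, deterministically
  if (nrow(centres) > n) {
    keep <- sort(sample.int(nrow(centres), n))
    centres <- centres[keep, , drop = FALSE]
  } else if (nrow(centres) < n) {
    extra <- validIdx[sample.int(nrow(validIdx), n - nrow(centres)), ,
                      drop = FALSE]
    centres <- rbind(centres, extra)
  }
  K <- nrow(centres)
  cint <- v[centres]
  crow <- centres[, 1]; ccol <- centres[, 2]

  labels <- matrix(NA_integer_, nr, nc)
  win <- ceiling(2 * S)
  for (it in seq_len(iterations)) {
    best <- matrix(Inf, nr, nc)
    labels[] <- NA_integer_
    for (k in seq_len(K)) {
      r1 <- max(1, round(crow[k]) - win); r2 <- min(nr, round(crow[k]) + win)
      c1 <- max(1, round(ccol[k]) - win); c2 <- min(nc, round(ccol[k]) + win)
      sub <- v[r1:r2, c1:c2, drop = FALSE]
      dI2 <- (sub - cint[k])^2
      dr <- (r1:r2) - crow[k]; dc <- (c1:c2) - ccol[k]
      ds2 <- outer(dr^2, dc^2, "+")
      D <- dI2 + (compactness / S)^2 * ds2
      D[!mask[r1:r2, c1:c2, drop = FALSE]] <- Inf
      better <- D < best[r1:r2, c1:c2, drop = FALSE]
      if (any(better, na.rm = TRUE)) {
        bi <- best[r1:r2, c1:c2, drop = FALSE]
        li <- labels[r1:r2, c1:c2, drop = FALSE]
        bi[better] <- D[better]
        li[better] <- k
        best[r1:r2, c1:c2] <- bi
        labels[r1:r2, c1:c2] <- li
      }
    }
    # orphan valid cells (outside every search window): nearest centre
    orphan <- which(mask & is.na(labels), arr.ind = TRUE)
    if (nrow(orphan)) {
      for (i in seq_len(nrow(orphan))) {
        d2 <- (crow - orphan[i, 1])^2 + (ccol - orphan[i, 2])^2
        labels[orphan[i, 1], orphan[i, 2]] <- which.min(d2)
      }
    }
    # update centres
    for (k in seq_len(K)) {
      memb <- which(labels == k, arr.ind = TRUE)
      if (!nrow(memb)) next
      crow[k] <- mean(memb[, 1]); ccol[k] <- mean(memb[, 2])
      cint[k] <- mean(v[memb])
    }
  }

  labels <- mergeFragments(labels, mask)
  # relabel 1..K' contiguously
  ids <- sort(unique(labels[!is.na(labels)]))
  labels[] <- match(labels, ids)
  new("SuperpixelSegmentation", labels = labels, nRequested = n,
      compactness = compactness, cellSize = raster@cellSize, seed = seed)
}

# merge disconnected fragments of each superpixel into the dominant
# 4-neighbour label; keeps each superpixel's largest component
mergeFragments <- function(labels, mask) {
  nr <- nrow(labels); nc <- ncol(labels)
  for (pass in 1:5) {
    changed <- FALSE
    for (k in sort(unique(labels[!is.na(labels)]))) {
      comp <- EBImage::bwlabel((!is.na(labels)) & labels == k)
      ncomp <- max(comp)
      if (ncomp <= 1) next
      sizes <- tabulate(comp[comp > 0], nbins = ncomp)
      keep <- which.max(sizes)
      for (f in seq_len(ncomp)) {
        if (f == keep) next
        cells <- which(comp == f, arr.ind = TRUE)
        # dominant neighbouring label outside the fragment
        nb <- integer(0)
        for (i in seq_len(nrow(cells))) {
          r <- cells[i, 1]; cc <- cells[i, 2]
          for (off in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
            rr <- r + off[1]; ccc <- cc + off[2]
            if (rr >= 1 && rr <= nr && ccc >= 1 && ccc <= nc &&
                !is.na(labels[rr, ccc]) && labels[rr, ccc] != k)
              nb <- c(nb, labels[rr, ccc])
          }
        }
        if (length(nb)) {
          tab <- table(nb)
          labels[cells] <- as.integer(names(tab)[which.max(tab)])
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  labels
}

#' Superpixel-count heuristic
#'
#' The number of superpixels needed to segment an echogram scales
#' approximately linearly with its length. Given calibration `pairs`
#' (length_m, n), fits the zero-intercept least-squares slope
#' `b = sum(x y) / sum(x^2)`; given a `length` alone, uses the slope
#' packaged from [slicCalibrationPairs()] (about 1.46 superpixels per
#' metre).
#'
#' @param lengthM echogram length in metres (optional).
#' @param pairs data.frame or matrix with columns length and n
#'   (optional; defaults to the packaged calibration pairs).
#' @return list with `slope` and, when `lengthM` is given, `n =
#'   round(slope * lengthM)`.
#' @export
superpixelCountHeuristic <- function(lengthM = NULL, pairs = NULL) {
  if (is.null(pairs)) pairs <- slicCalibrationPairs()[, c("length", "n")]
  pairs <- as.matrix(pairs)
  x <- pairs[, 1]; y <- pairs[, 2]
  if (!length(x) || any(x <= 0)) stop("pair lengths must be positive")
  b <- sum(x * y) / sum(x^2)
  out <- list(slope = b)
  if (!is.null(lengthM)) {
    if (any(lengthM <= 0)) stop("length must be positive")
    out$n <- round(b * lengthM)
  }
  out
}

#' Packaged superpixel calibration measurements
#'
#' Five echograms' (length, mean superpixel area, superpixel count)
#' triples used to calibrate the count heuristic.
#'
#' @return data.frame with columns length (m), area (m^2), n.
#' @export
slicCalibrationPairs <- function() {
  data.frame(length = c(183, 290, 422, 544, 646),
             area = c(106, 121, 146, 130, 124),
             n = c(125, 300, 700, 900, 900))
}

#' GLCM texture features per superpixel
#'
#' Tabulates, for each superpixel, only the pixel pairs whose reference
#' and offset pixels both lie inside that superpixel (and are valid),
#' then computes the standard metrics. Superpixels with zero countable
#' pairs are undefined. When superpixels are exact square tiles this
#' reproduces the windowed GLCM.
#'
#' @param raster an [IntensityRaster-class].
#' @param seg a [SuperpixelSegmentation-class] aligned to the raster.
#' @param params a [GlcmParams-class] (d, theta, N, symmetric used).
#' @return data.frame: id, nCells, area_m2, E, H, Hprime, muG, varG,
#'   corrG.
#' @export
superpixelTexture <- function(raster, seg, params) {
  if (!all(dim(seg@labels) == dim(raster@values)))
    stop("segmentation is not aligned to the raster")
  q <- quantizeRaster(raster, params@N)
  W <- q@values
  lab <- seg@labels
  off <- glcmOffset(as.integer(params@d), params@theta)
  nr <- nrow(W); nc <- ncol(W)
  dr <- off[1]; dc <- off[2]
  r1 <- max(1, 1 - dr); r2 <- min(nr, nr - dr)
  c1 <- max(1, 1 - dc); c2 <- min(nc, nc - dc)
  ids <- sort(unique(lab[!is.na(lab)]))
  N <- as.integer(params@N)
  pairIJ <- NULL
  if (r1 <= r2 && c1 <= c2) {
    i <- W[r1:r2, c1:c2]
    j <- W[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc)]
    li <- lab[r1:r2, c1:c2]
    lj <- lab[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc)]
    ok <- !is.na(i) & !is.na(j) & !is.na(li) & !is.na(lj) & li == lj
    pairIJ <- data.frame(id = li[ok], i = i[ok], j = j[ok])
  }
  out <- lapply(ids, function(id) {
    feats <- c(E = NA_real_, H = NA_real_, Hprime = NA_real_,
               muG = NA_real_, varG = NA_real_, corrG = NA_real_)
    nCells <- sum(lab == id, na.rm = TRUE)
    if (!is.null(pairIJ)) {
      ij <- pairIJ[pairIJ$id == id, c("i", "j"), drop = FALSE]
      if (params@symmetric && nrow(ij))
        ij <- rbind(ij, setNames(ij[, 2:1], c("i", "j")))
      if (nrow(ij)) {
        counts <- tabulate(ij$i * N + ij$j + 1, nbins = N * N)
        V <- matrix(counts, N, N, byrow = TRUE)
        feats <- glcmFeatures(list(P = V / sum(V)))
      }
    }
    data.frame(id = id, nCells = nCells,
               area_m2 = nCells * raster@cellSize^2, t(feats))
  })
  do.call(rbind, out)
}
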