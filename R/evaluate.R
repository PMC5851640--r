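## Skill assessment and map summaries: confusion matrices,
## precision/recall/F1, areal fractions and their downstream convergence,
## map comparison.

#' Confusion matrix of a classification map against labelled polygons
#'
#' Windows are assigned an observed class by centroid containment in the
#' polygons of the requested role; the predicted class is the window's
#' map label. Null/other predictions are tallied as extra predicted
#' columns. Nodata windows are excluded. A row-percent view (each
#' observed row summing to 100) accompanies the counts.
#'
#' @param map a [ClassificationMap-class].
#' @param polys a [SubstratePolygonSet-class].
#' @param roles polygon roles used as truth (default "validation").
#' @return list with `counts` (observed x predicted), `rowPercent`, and
#'   `n` (evaluated windows).
#' @export
confusionMap <- function(map, polys, roles = "validation") {
  w <- map@windows
  pts <- cbind(w$easting, w$northing)
  obs <- rep(NA_character_, nrow(w))
  for (i in seq_along(polys@polygons)) {
    if (!polys@roles[i] %in% roles) next
    obs[pointsInRing(polys@polygons[[i]], pts)] <- polys@labels[i]
  }
  keep <- !is.na(obs) & w$label != "nodata"
  if (!any(keep)) stop("no overlap between map and labelled polygons")
  observed <- intersect(polys@vocabulary, unique(obs[keep]))
  extras <- intersect(c("null", "other"), unique(w$label[keep]))
  predicted <- c(intersect(polys@vocabulary, map@classes), extras)
  counts <- table(factor(obs[keep], levels = observed),
                  factor(w$label[keep], levels = predicted))
  counts <- unclass(counts)
  rowPercent <- 100 * counts / pmax(rowSums(counts), 1)
  list(counts = counts, rowPercent = rowPercent, n = sum(keep))
}

#' Harmonic-mean F1 score
#'
#' `F1 = 2 P R / (P + R)`, with the convention F1 = 0 when P + R = 0.
#'
#' @param P precision, R recall (same length).
#' @param R recall.
#' @return F1, same length.
#' @export
f1Score <- function(P, R) {
  ifelse(P + R > 0, 2 * P * R / (P + R), 0)
}

#' Per-class precision, recall and F1 from a confusion matrix
#'
#' Precision of class c = true positives / all windows predicted c
#' (null/other predictions are never false positives of a substrate);
#' recall = true positives / all windows observed c (null/other
#' predictions count against recall). Macro averages are unweighted
#' class means. Classes absent from the truth get NA and are flagged.
#'
#' @param cm result of [confusionMap()] (or a list with a `counts`
#'   matrix).
#' @return data.frame with one row per class plus a "macro" row:
#'   class, precision, recall, f1, support.
#' @export
skillScores <- function(cm) {
  counts <- cm$counts
  substrates <- setdiff(colnames(counts), c("null", "other"))
  rows <- lapply(substrates, function(cl) {
    tp <- if (cl %in% rownames(counts)) counts[cl, cl] else 0
    predAs <- sum(counts[, cl])
    support <- if (cl %in% rownames(counts)) sum(counts[cl, ]) else 0
    P <- if (predAs > 0) tp / predAs else 0
    R <- if (support > 0) tp / support else NA_real_
    data.frame(class = cl, precision = P, recall = R,
               f1 = if (is.na(R)) NA_real_ else f1Score(P, R),
               support = support)
  })
  out <- do.call(rbind, rows)
  macro <- data.frame(class = "macro",
                      precision = mean(out$precision, na.rm = TRUE),
                      recall = mean(out$recall, na.rm = TRUE),
                      f1 = mean(out$f1, na.rm = TRUE),
                      support = sum(out$support))
  rbind(out, macro)
}

#' Areal fraction of each substrate in a map
#'
#' Fractions over windows carrying a substrate label (null/other/nodata
#' excluded); they sum to 1.
#'
#' @param map a [ClassificationMap-class].
#' @return named numeric vector of fractions.
#' @export
arealFractions <- function(map) {
  lab <- map@windows$label
  lab <- lab[lab %in% map@classes]
  if (!length(lab)) stop("no classified windows")
  tab <- table(factor(lab, levels = map@classes))
  setNames(as.numeric(tab) / length(lab), map@classes)
}

#' Attach downstream distance to map windows
#'
#' Distance is the arc-length position of each window centroid projected
#' onto a supplied track polyline; without a track, the fallback is the
#' signed projection onto the first principal axis of the classified
#' windows, shifted to start at 0.
#'
#' @param map a [ClassificationMap-class].
#' @param track optional two-column (easting, northing) polyline.
#' @return the map with a `distance` column filled (m).
#' @export
assignDownstreamDistance <- function(map, track = NULL) {
  w <- map@windows
  pts <- cbind(w$easting, w$northing)
  if (is.null(track)) {
    keep <- w$label %in% c(map@classes, "null", "other")
    pc <- prcomp(pts[keep, , drop = FALSE], center = TRUE, scale. = FALSE)
    d <- as.numeric(scale(pts, center = pc$center, scale = FALSE) %*%
                      pc$rotation[, 1])
    d <- d - min(d[keep])
  } else {
    track <- as.matrix(track)
    seg <- diff(track)
    segLen <- sqrt(rowSums(seg^2))
    cum0 <- c(0, cumsum(segLen))
    d <- vapply(seq_len(nrow(pts)), function(i) {
      best <- Inf; at <- 0
      for (s in seq_len(nrow(seg))) {
        v <- seg[s, ]
        t0 <- sum((pts[i, ] - track[s, ]) * v) / sum(v^2)
        t0 <- min(max(t0, 0), 1)
        p <- track[s, ] + t0 * v
        dist2 <- sum((pts[i, ] - p)^2)
        if (dist2 < best) { best <- dist2; at <- cum0[s] + t0 * segLen[s] }
      }
      at
    }, numeric(1))
  }
  w$distance <- d
  map@windows <- w
  map
}

#' Cumulative areal fractions as a function of downstream distance
#'
#' Orders windows by downstream distance and, for each prefix, reports
#' per-class fractions among the classified windows seen so far. The
#' full-prefix values equal [arealFractions()]. Used to judge how much
#' reach must be scanned before class proportions converge.
#'
#' @param map a [ClassificationMap-class] with a `distance` column (see
#'   [assignDownstreamDistance()]).
#' @return data.frame (distance, class, fraction), long format.
#' @export
cumulativeFractions <- function(map) {
  w <- map@windows
  if (is.null(w$distance) || all(is.na(w$distance)))
    stop("windows carry no downstream distance; call assignDownstreamDistance()")
  w <- w[w$label %in% map@classes, , drop = FALSE]
  if (!nrow(w)) stop("no classified windows")
  w <- w[order(w$distance), , drop = FALSE]
  out <- lapply(map@classes, function(cl) {
    frac <- cumsum(w$label == cl) / seq_len(nrow(w))
    data.frame(distance = w$distance, class = cl, fraction = frac)
  })
  do.call(rbind, out)
}

#' Compare two classification maps on a common lattice
#'
#' Windows are matched by lattice address. Reports per-class absolute
#' areal-fraction differences (percentage points) and the cellwise
#' agreement rate over windows classified in both maps.
#'
#' @param mapA,mapB [ClassificationMap-class] objects on the same window
#'   lattice.
#' @return list with `fractionDiff` (per class, percent),
#'   `agreement` (fraction of co-classified windows with equal labels)
#'   and `nCompared`.
#' @export
compareMaps <- function(mapA, mapB) {
  a <- mapA@windows; b <- mapB@windows
  key <- function(x) paste(x$wrow, x$wcol)
  m <- match(key(a), key(b))
  ok <- !is.na(m)
  if (!any(ok)) stop("maps have disjoint extents")
  la <- a$label[ok]; lb <- b$label[m[ok]]
  classes <- union(mapA@classes, mapB@classes)
  both <- la %in% classes & lb %in% classes
  if (!any(both)) stop("no co-classified windows")
  fa <- table(factor(la[la %in% classes], levels = classes))
  fb <- table(factor(lb[lb %in% classes], levels = classes))
  fa <- as.numeric(fa) / sum(fa); fb <- as.numeric(fb) / sum(fb)
  list(fractionDiff = setNames(100 * abs(fa - fb), classes),
       agreement = mean(la[both] == lb[both]),
       nCompared = sum(both))
}

#' Export a classification map as CSV
#'
#' @param map a [ClassificationMap-class].
#' @param path output path.
#' @export
writeClassificationCsv <- function(map, path) {
  write.csv(map@windows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeClassificationCsv
#' @param classes substrate vocabulary of the stored map.
#' @param method classifier tag ("lsq" or "gmm").
#' @export
readClassificationCsv <- function(path, classes = c("sand", "gravel",
                                                    "boulders"),
                                  method = "lsq") {
  w <- read.csv(path, stringsAsFactors = FALSE)
  new("ClassificationMap", windows = w,
      classes = intersect(classes, unique(c(classes, w$label))),
      method = method)
}

#' Integer-coded label matrix of a classification map
#'
#' Codes: 0 nodata, 1 sand, 2 gravel, 3 boulders, 9 null/other.
#'
#' @param map a [ClassificationMap-class].
#' @return integer matrix on the window lattice.
#' @export
labelMatrix <- function(map) {
  w <- map@windows
  codes <- c(nodata = 0L, sand = 1L, gravel = 2L, boulders = 3L,
             null = 9L, other = 9L)
  nr <- max(w$wrow) + 1L; nc <- max(w$wcol) + 1L
  m <- matrix(0L, nr, nc)
  m[cbind(w$wrow + 1L, w$wcol + 1L)] <- codes[w$label]
  m
}
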