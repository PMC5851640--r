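# Independent brute-force oracles. These deliberately share no code with
# the package implementation: plain loops and direct formula evaluation.

# exhaustive nearest-point search over all point-node pairs
oracleNearestGrid <- function(cloud, cellSize, searchRadius, extent) {
  nc <- round((extent[2] - extent[1]) / cellSize)
  nr <- round((extent[4] - extent[3]) / cellSize)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      cx <- extent[1] + (cc - 0.5) * cellSize
      cy <- extent[4] - (r - 0.5) * cellSize
      bestD <- Inf; bestI <- NA
      for (i in seq_len(nrow(cloud))) {
        d <- sqrt((cloud$easting[i] - cx)^2 + (cloud$northing[i] - cy)^2)
        if (d <= searchRadius && d < bestD - 1e-12) {
          bestD <- d; bestI <- i
        }
      }
      if (!is.na(bestI)) out[r, cc] <- cloud$intensity[bestI]
    }
  }
  out
}

# exhaustive directed pair enumeration for one offset over a masked
# window of quantized levels (NA = invalid)
oracleGlcm <- function(W, d, theta, N, symmetric = FALSE) {
  dr <- switch(as.character(theta), "0" = 0, "45" = -d, "90" = -d,
               "135" = -d)
  dc <- switch(as.character(theta), "0" = d, "45" = d, "90" = 0,
               "135" = -d)
  V <- matrix(0, N, N)
  for (r in seq_len(nrow(W))) {
    for (cc in seq_len(ncol(W))) {
      r2 <- r + dr; c2 <- cc + dc
      if (r2 < 1 || r2 > nrow(W) || c2 < 1 || c2 > ncol(W)) next
      i <- W[r, cc]; j <- W[r2, c2]
      if (is.na(i) || is.na(j)) next
      V[i + 1, j + 1] <- V[i + 1, j + 1] + 1
      if (symmetric) V[j + 1, i + 1] <- V[j + 1, i + 1] + 1
    }
  }
  V
}

# direct summation of the scalar metrics from a probability matrix
oracleGlcmMetrics <- function(P) {
  N <- nrow(P)
  H <- 0; E <- 0; mu <- 0
  for (i in 0:(N - 1)) for (j in 0:(N - 1)) {
    p <- P[i + 1, j + 1]
    H <- H + p / (1 + (i - j)^2)
    if (p > 0) E <- E - p * log(p)
    mu <- mu + i * p
  }
  vg <- 0
  for (i in 0:(N - 1)) for (j in 0:(N - 1))
    vg <- vg + (i - mu)^2 * P[i + 1, j + 1]
  c(E = E, H = H, muG = mu, varG = vg)
}

# brute-force minimiser of || A u - o ||^2 over the u simplex at the
# given grid resolution (the abundance-sum penalty vanishes on the
# simplex, so this is the oracle for the fully constrained unmixing)
oracleSimplexUnmix <- function(A, o, resolution = 1e-3) {
  m <- round(1 / resolution)
  stopifnot(ncol(A) == 3)
  a <- rep(0:m, times = m + 1 - 0:m)
  b <- unlist(lapply(0:m, function(ai) 0:(m - ai)))
  U <- rbind(a, b, m - a - b) / m          # 3 x nGrid simplex points
  R <- A %*% U - o                         # residuals per grid point
  unname(U[, which.min(colSums(R^2))])     # first minimum: deterministic
}

# naive per-component mixture posterior by direct density evaluation
oraclePosterior <- function(v, weights, means, covs) {
  q <- length(weights)
  D <- length(v)
  dens <- numeric(q)
  for (k in seq_len(q)) {
    S <- covs[[k]]
    dev <- v - means[k, ]
    dens[k] <- weights[k] * (2 * pi)^(-D / 2) * det(S)^(-0.5) *
      exp(-0.5 * as.numeric(t(dev) %*% solve(S) %*% dev))
  }
  dens / sum(dens)
}

# precision/recall/F1 computed by explicit counting from a counts matrix
oracleSkill <- function(counts, cl) {
  tp <- counts[cl, cl]
  fp <- sum(counts[, cl]) - tp
  fn <- sum(counts[cl, ]) - tp
  P <- if (tp + fp > 0) tp / (tp + fp) else 0
  R <- tp / (tp + fn)
  f1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  c(precision = P, recall = R, f1 = f1)
}
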