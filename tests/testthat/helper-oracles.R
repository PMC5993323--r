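# Independent brute-force implementations used as oracles. These
# deliberately avoid the package's computational paths (rolling sums,
# leave-one-out updates, streaming accumulation).

# Weighted correlation via stats::cov.wt (library route, not the package's).
oracleWeightedPearson <- function(x, y, w) {
  stats::cov.wt(cbind(x, y), wt = w / sum(w), cor = TRUE)$cor[1L, 2L]
}

# Sliding-window correlation by explicit windowing.
oracleSlidingWindow <- function(v, L) {
  tLen <- nrow(v)
  h <- (L - 1L) %/% 2L
  est <- rep(NA_real_, tLen)
  for (t in (h + 1L):(tLen - h)) {
    idx <- (t - h):(t + h)
    est[t] <- stats::cor(v[idx, 1L], v[idx, 2L])
  }
  est
}

# Tapered sliding window by explicit weighting of each window.
oracleTaperedWindow <- function(v, L, variance) {
  tLen <- nrow(v)
  h <- (L - 1L) %/% 2L
  w <- exp(-((-h):h)^2 / (2 * variance))
  est <- rep(NA_real_, tLen)
  for (t in (h + 1L):(tLen - h)) {
    idx <- (t - h):(t + h)
    est[t] <- oracleWeightedPearson(v[idx, 1L], v[idx, 2L], w)
  }
  est
}

# Jackknife correlation by explicitly dropping each point.
oracleJackknife <- function(v) {
  tLen <- nrow(v)
  vapply(seq_len(tLen), function(t)
    -stats::cor(v[-t, 1L], v[-t, 2L]), 1)
}

# Leave-n-out correlation by explicitly dropping the centred block.
oracleLeaveNOut <- function(v, n) {
  tLen <- nrow(v)
  vapply(seq_len(tLen), function(t) {
    lo <- max(1L, t - (n - 1L) %/% 2L)
    hi <- min(tLen, t + n %/% 2L)
    keep <- setdiff(seq_len(tLen), lo:hi)
    -stats::cor(v[keep, 1L], v[keep, 2L])
  }, 1)
}

# Spatial-distance estimates: full weight matrix, global min-max scaling,
# self weights 1, cov.wt correlations.
oracleSpatialDistance <- function(space, x, y) {
  tLen <- nrow(space)
  D <- as.matrix(stats::dist(space))
  diag(D) <- NA
  W <- 1 / D
  fin <- is.finite(W)
  W[!fin & !is.na(D)] <- max(W[fin], na.rm = TRUE)
  gmin <- min(W, na.rm = TRUE)
  gmax <- max(W, na.rm = TRUE)
  W <- (W - gmin) / (gmax - gmin)
  diag(W) <- 1
  vapply(seq_len(tLen), function(t)
    oracleWeightedPearson(x, y, W[t, ]), 1)
}

# MTD by direct evaluation of the definition.
oracleMtd <- function(v, sw) {
  tLen <- nrow(v)
  dfx <- diff(v[, 1L]); dfy <- diff(v[, 2L])
  raw <- c(NA_real_, dfx * dfy / (stats::sd(dfx) * stats::sd(dfy)))
  est <- rep(NA_real_, tLen)
  h <- (sw - 1L) %/% 2L
  for (t in seq_len(tLen)) {
    idx <- (t - h):(t + h)
    if (min(idx) >= 1L && max(idx) <= tLen && !anyNA(raw[idx]))
      est[t] <- mean(raw[idx])
  }
  est
}

# WAIC by naive spreadsheet-style loops over an explicit S x N
# log-likelihood matrix.
oracleWaic <- function(draws, x, y) {
  S <- nrow(draws); N <- length(x)
  ll <- matrix(NA_real_, S, N)
  for (s in seq_len(S))
    for (i in seq_len(N))
      ll[s, i] <- stats::dnorm(y[i],
                               draws[s, "intercept"] + draws[s, "slope"] * x[i],
                               draws[s, "sigma"], log = TRUE)
  lppd <- numeric(N); p <- numeric(N)
  for (i in seq_len(N)) {
    lppd[i] <- log(mean(exp(ll[, i])))
    p[i] <- stats::var(ll[, i])
  }
  contrib <- -2 * (lppd - p)
  list(waic = sum(contrib), se = sqrt(N * stats::var(contrib)))
}

# Build a PosteriorFit with externally supplied draws (for WAIC oracles).
manualFit <- function(draws, x, y) {
  new("PosteriorFit", draws = draws,
      chain = rep(1L, nrow(draws)), x = x, y = y,
      spec = trackingModelSpec(draws = nrow(draws) + 1L, burn = 1L,
                               chains = 1L),
      diagnostics = list())
}

# Minimal TVCSeries for post-processing tests.
newSeries <- function(estimate, valid, method = "test") {
  est <- as.numeric(estimate)
  est[!valid] <- NA_real_
  new("TVCSeries", estimate = est, valid = valid, method = method,
      params = list())
}

# Pair with an exactly known constant generating covariance.
constantCovPair <- function(tLen, r, seed) {
  track <- new("CovarianceTrack", r = rep(r, tLen), muR = r, sigmaR = 1e-6,
               alphaR = 0, clampBound = 0.999)
  simulateWithTrack(track, seed = seed)
}

# The stepped-covariance demonstration data: covariance 0.8 dropping by
# 0.2 every `step` points.
steppedCovPair <- function(tLen = 10000L, step = 2000L, seed = 1L) {
  levels <- c(0.8, 0.6, 0.4, 0.2, 0)
  r <- rep(levels, each = step, length.out = tLen)
  track <- new("CovarianceTrack", r = r, muR = 0, sigmaR = 1e-6,
               alphaR = 0, clampBound = 0.999)
  simulateWithTrack(track, seed = seed)
}
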