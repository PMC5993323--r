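#' @include AllClasses.R
NULL

#' Construct a window specification
#'
#' @param length odd window length in time points (15 and 29 are the
#'   benchmark defaults, i.e. 30 s and 58 s at TR = 2 s).
#' @param taperVariance optional Gaussian taper variance in squared time
#'   points (the tapered benchmark methods use 10); `NULL` for an
#'   untapered window.
#' @return A [WindowSpec].
#' @export
windowSpec <- function(length, taperVariance = NULL) {
  new("WindowSpec", length = as.integer(length),
      taperVariance = taperVariance)
}

newTVCSeries <- function(estimate, valid, method, params = list()) {
  new("TVCSeries", estimate = as.numeric(estimate), valid = valid,
      method = method, params = params)
}

asPairMatrix <- function(pair) {
  if (is(pair, "BivariatePair")) return(pair@values)
  if (is(pair, "SimulatedDataset")) return(pair@pair@values)
  if (is.matrix(pair) && ncol(pair) == 2L) return(pair)
  stop("'pair' must be a BivariatePair, SimulatedDataset, or T x 2 matrix")
}

clampCor <- function(r) pmin(pmax(r, -1), 1)

#' Weighted Pearson correlation
#'
#' Pearson correlation with nonnegative observation weights: weighted
#' covariance over the product of weighted standard deviations, all moments
#' computed about the weighted means. Uniform weights reduce to the plain
#' Pearson correlation; zero weights exclude points entirely.
#'
#' @param x,y numeric vectors of equal length.
#' @param w nonnegative weights of the same length, at least two positive.
#' @return Correlation in `[-1, 1]`.
#' @examples
#' weightedPearson(1:4, c(1, 2, 3, 5), c(1, 1, 1, 0))  # 1: first 3 linear
#' @export
weightedPearson <- function(x, y, w) {
  n <- length(x)
  if (length(y) != n || length(w) != n)
    stop("'x', 'y', 'w' must have equal length")
  if (any(w < 0)) stop("weights must be nonnegative")
  if (sum(w > 0) < 2L) stop("need at least two positive weights")
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  dx <- x - mx
  dy <- y - my
  vx <- sum(w * dx * dx)
  vy <- sum(w * dy * dy)
  if (vx <= 0 || vy <= 0)
    stop("degenerate input: zero weighted variance")
  clampCor(sum(w * dx * dy) / sqrt(vx * vy))
}

# Rolling weighted sufficient statistics via symmetric convolution; returns
# the correlation sequence with NA outside the fully-covered centre points.
rollingCorrelation <- function(x, y, kernel) {
  sw <- sum(kernel)
  f <- function(v) as.numeric(stats::filter(v, kernel, sides = 2))
  sx <- f(x);  sy <- f(y)
  sxx <- f(x * x); syy <- f(y * y); sxy <- f(x * y)
  num <- sw * sxy - sx * sy
  den2 <- (sw * sxx - sx^2) * (sw * syy - sy^2)
  r <- ifelse(den2 > 0, num / sqrt(pmax(den2, 0)), NA_real_)
  clampCor(r)
}

#' Sliding-window correlation
#'
#' The estimate at `t` is the Pearson correlation over the
#' `window@length` points centred at `t`; the window then slides one step.
#' The `(length - 1) / 2` points at each edge have no complete window and
#' are marked invalid (for T = 10000 and length 29, 9972 points remain).
#'
#' @param pair a [BivariatePair], [SimulatedDataset], or T x 2 matrix.
#' @param window a [WindowSpec] without taper (or an odd integer length).
#' @return A [TVCSeries] labelled `"SW-<length>"`.
#' @export
slidingWindow <- function(pair, window = windowSpec(29)) {
  if (is.numeric(window)) window <- windowSpec(window)
  if (!is.null(window@taperVariance))
    stop("use taperedSlidingWindow() for a tapered window")
  v <- asPairMatrix(pair)
  L <- window@length
  tLen <- nrow(v)
  if (L > tLen) stop("window longer than the series")
  r <- rollingCorrelation(v[, 1L], v[, 2L], rep(1, L))
  h <- (L - 1L) %/% 2L
  valid <- rep(FALSE, tLen)
  valid[(h + 1L):(tLen - h)] <- TRUE
  valid <- valid & !is.na(r)
  newTVCSeries(r, valid, sprintf("SW-%d", L), list(length = L))
}

#' Gaussian-tapered sliding-window correlation
#'
#' As [slidingWindow()], but each in-window point is weighted by a Gaussian
#' centred at `t` with variance `window@taperVariance` (zero weight outside
#' the window), and the estimate is the weighted Pearson correlation. As
#' the taper variance grows the weights flatten and the estimate converges
#' to the untapered sliding window. The benchmark's tapered methods use a
#' taper sd of 10 time points (variance 100), a gentle taper relative to
#' the window lengths of 15 and 29.
#'
#' @param pair a [BivariatePair], [SimulatedDataset], or T x 2 matrix.
#' @param window a [WindowSpec] with `taperVariance` set (default length
#'   29, variance 100).
#' @return A [TVCSeries] labelled `"TSW-<length>"`.
#' @export
taperedSlidingWindow <- function(pair, window = windowSpec(29, 100)) {
  if (is.null(window@taperVariance))
    stop("'window' must carry a taper variance")
  v <- asPairMatrix(pair)
  L <- window@length
  tLen <- nrow(v)
  if (L > tLen) stop("window longer than the series")
  h <- (L - 1L) %/% 2L
  kernel <- exp(-((-h):h)^2 / (2 * window@taperVariance))
  r <- rollingCorrelation(v[, 1L], v[, 2L], kernel)
  valid <- rep(FALSE, tLen)
  valid[(h + 1L):(tLen - h)] <- TRUE
  valid <- valid & !is.na(r)
  newTVCSeries(r, valid, sprintf("TSW-%d", L),
               list(length = L, taperVariance = window@taperVariance))
}

#' Spatial-distance connectivity
#'
#' For each time point `t`, a weight vector is built from the inverse
#' Euclidean distance between the amplitude vectors at `t` and every other
#' time point `u` (similar activation profiles get large weights). The
#' whole off-diagonal weight matrix is min-max scaled to `[0, 1]` in one
#' global operation, so relative proximity stays comparable across target
#' time points, and the self weight is set to 1; the estimate at `t` is
#' the weighted Pearson correlation of the pair under `t`'s weights.
#' Every time point is estimable, and because the weights depend only on
#' amplitudes the estimates are permutation-invariant.
#'
#' In `"bivariate"` mode the distances use only the two series of each
#' edge; in `"multivariate"` mode all `R` columns contribute one shared
#' weight set per time point (one weight vector per time point rather than
#' per edge and time point). Coincident points (zero distance) receive the
#' largest finite inverse distance in that weight vector before scaling.
#'
#' @param series a [BivariatePair], [SimulatedDataset], or T x R matrix
#'   (R >= 2) with a header of ROI labels if column names are set.
#' @param distance distance metric; only `"euclidean"` is implemented.
#' @param mode `"bivariate"` (default) or `"multivariate"`.
#' @return A [TVCSeries] for a 2-column input; a named list of
#'   [TVCSeries], one per column pair, for R > 2.
#' @export
spatialDistanceTvc <- function(series, distance = "euclidean",
                               mode = c("bivariate", "multivariate")) {
  mode <- match.arg(mode)
  distance <- match.arg(distance, "euclidean")
  v <- if (is.matrix(series)) series else asPairMatrix(series)
  if (!is.matrix(v) || ncol(v) < 2L) stop("'series' must have R >= 2 columns")
  nR <- ncol(v)
  labels <- colnames(v)
  if (is.null(labels)) labels <- paste0("roi", seq_len(nR))
  pairs <- utils::combn(nR, 2L)
  out <- vector("list", ncol(pairs))
  names(out) <- apply(pairs, 2L, function(p)
    paste(labels[p], collapse = "-"))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    space <- if (mode == "bivariate") v[, c(i, j), drop = FALSE] else v
    est <- cpp_sd_tvc(space, v[, i], v[, j])
    out[[k]] <- newTVCSeries(clampCor(est), rep(TRUE, nrow(v)), "SD",
                             list(distance = distance, mode = mode,
                                  edge = names(out)[k]))
  }
  if (length(out) == 1L) out[[1L]] else out
}

#' Jackknife (leave-one-out) correlation
#'
#' The estimate at `t` is minus the Pearson correlation over all time
#' points except `t`, with the means also computed excluding `t`. The sign
#' flip corrects the inversion inherent to leaving points out: removing a
#' concordant point lowers the remaining correlation. Every time point is
#' estimable and the estimates are permutation-invariant. Absolute spread
#' shrinks as the series grows (variance compression), so estimates are
#' meaningful relative to one another and are usually standardized before
#' further analysis.
#'
#' Computed via leave-one-out sufficient-statistic updates in O(T); a naive
#' O(T^2) evaluation gives the same values to floating-point tolerance.
#'
#' @param pair a [BivariatePair], [SimulatedDataset], or T x 2 matrix.
#' @return A [TVCSeries] labelled `"JC"` with all points valid.
#' @export
jackknifeCorrelation <- function(pair) {
  v <- asPairMatrix(pair)
  tLen <- nrow(v)
  if (tLen < 3L) stop("jackknife correlation needs at least 3 time points")
  x <- v[, 1L] - mean(v[, 1L])
  y <- v[, 2L] - mean(v[, 2L])
  n1 <- tLen - 1
  sx <- sum(x) - x;    sy <- sum(y) - y
  sxx <- sum(x * x) - x * x
  syy <- sum(y * y) - y * y
  sxy <- sum(x * y) - x * y
  den2 <- (n1 * sxx - sx^2) * (n1 * syy - sy^2)
  if (any(den2 <= 0))
    stop("degenerate input: a leave-one-out subseries is constant")
  r <- -(n1 * sxy - sx * sy) / sqrt(den2)
  newTVCSeries(clampCor(r), rep(TRUE, tLen), "JC", list())
}

#' Leave-n-out correlation
#'
#' Generalizes [jackknifeCorrelation()] by excluding the `n` consecutive
#' points centred at `t` (truncated at the series boundaries, so at least
#' `T - n` points always remain) and negating the Pearson correlation of
#' the remainder. `n = 1` reproduces the jackknife exactly; mid-range `n`
#' mirrors a window-of-length-`n` sliding-window estimate up to sign and
#' scale.
#'
#' @param pair a [BivariatePair], [SimulatedDataset], or T x 2 matrix.
#' @param n number of consecutive points to exclude, `1 <= n <= T - 2`.
#' @return A [TVCSeries] labelled `"LNO-<n>"` with all points valid.
#' @export
leaveNOutCorrelation <- function(pair, n = 1L) {
  v <- asPairMatrix(pair)
  tLen <- nrow(v)
  n <- as.integer(n)
  if (n < 1L || n > tLen - 2L) stop("'n' must lie in [1, T - 2]")
  x <- v[, 1L] - mean(v[, 1L])
  y <- v[, 2L] - mean(v[, 2L])
  tIdx <- seq_len(tLen)
  lo <- pmax(1L, tIdx - (n - 1L) %/% 2L)
  hi <- pmin(tLen, tIdx + n %/% 2L)
  cs <- function(v) c(0, cumsum(v))
  block <- function(c) c[hi + 1L] - c[lo]
  m <- tLen - (hi - lo + 1L)
  sx <- sum(x) - block(cs(x));      sy <- sum(y) - block(cs(y))
  sxx <- sum(x * x) - block(cs(x * x))
  syy <- sum(y * y) - block(cs(y * y))
  sxy <- sum(x * y) - block(cs(x * y))
  den2 <- (m * sxx - sx^2) * (m * syy - sy^2)
  if (any(den2 <= 0))
    stop("degenerate input: a leave-n-out subseries is constant")
  r <- -(m * sxy - sx * sy) / sqrt(den2)
  newTVCSeries(clampCor(r), rep(TRUE, tLen), sprintf("LNO-%d", n),
               list(n = n))
}

#' Multiplication of temporal derivatives
#'
#' First-differences each series, forms the per-time-point product of the
#' two derivatives scaled by the product of the derivatives' standard
#' deviations (computed over the whole derivative series), and smooths the
#' resulting coupling series with a centred boxcar average (default length
#' 7). The result is on a product scale, not a correlation scale, so it is
#' not Fisher-transformed. The first point (no derivative) and the
#' smoothing edges are invalid.
#'
#' @param pair a [BivariatePair], [SimulatedDataset], or T x 2 matrix.
#' @param smoothWindow odd boxcar length (default 7); 1 disables smoothing.
#' @return A [TVCSeries] labelled `"MTD-<smoothWindow>"`.
#' @export
mtd <- function(pair, smoothWindow = 7L) {
  v <- asPairMatrix(pair)
  tLen <- nrow(v)
  smoothWindow <- as.integer(smoothWindow)
  if (smoothWindow < 1L || smoothWindow %% 2L == 0L)
    stop("'smoothWindow' must be a positive odd integer")
  if (tLen < smoothWindow + 1L)
    stop("series too short for the requested smoothing window")
  dfx <- diff(v[, 1L])
  dfy <- diff(v[, 2L])
  sdx <- stats::sd(dfx)
  sdy <- stats::sd(dfy)
  if (sdx == 0 || sdy == 0)
    stop("degenerate input: a derivative series has zero variance")
  raw <- c(NA_real_, dfx * dfy / (sdx * sdy))
  if (smoothWindow == 1L) {
    est <- raw
  } else {
    est <- as.numeric(stats::filter(raw, rep(1 / smoothWindow, smoothWindow),
                                    sides = 2))
  }
  valid <- !is.na(est)
  est[!valid] <- NA_real_
  newTVCSeries(est, valid, sprintf("MTD-%d", smoothWindow),
               list(smoothWindow = smoothWindow, scale = "product"))
}
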