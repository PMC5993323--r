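#' Construct a tracking-model sampler specification
#'
#' Settings for the Bayesian linear model
#' \deqn{y_i \sim N(\alpha + \beta x_i, \sigma), \quad
#'       \alpha, \beta \sim N(0, 1), \quad \sigma \sim N^+(0, 1)}
#' that regresses the standardized ground-truth covariance on a method's
#' standardized estimate.
#'
#' @param draws MCMC draws per chain (default 5500).
#' @param burn initial draws discarded per chain (default 500).
#' @param chains number of chains (default 2, pooled after burn-in).
#' @param seed optional integer sampler seed.
#' @return A [TrackingModelSpec].
#' @export
trackingModelSpec <- function(draws = 5500L, burn = 500L, chains = 2L,
                              seed = NULL) {
  new("TrackingModelSpec", draws = as.integer(draws), burn = as.integer(burn),
      chains = as.integer(chains), seed = seed)
}

# log full conditional of sigma (up to a constant):
# -n log(sigma) - RSS / (2 sigma^2) - sigma^2 / 2   [HalfNormal(0,1) prior]
sigmaLogTarget <- function(s, n, rss) {
  -n * log(s) - rss / (2 * s * s) - s * s / 2
}

# Numerical floor for the noise sd: with exactly collinear data the
# conditional density of sigma is unbounded at 0, so the sampler pins
# degenerate fits at this floor instead of collapsing to underflow.
SIGMA_FLOOR <- 1e-6

# Univariate slice sampler (stepping out + shrinkage) on sigma > floor.
sliceSigma <- function(s0, n, rss, w) {
  s0 <- max(s0, SIGMA_FLOOR)
  f0 <- sigmaLogTarget(s0, n, rss)
  logy <- f0 - stats::rexp(1L)
  lo <- s0 - w * stats::runif(1L)
  hi <- lo + w
  while (lo > SIGMA_FLOOR && sigmaLogTarget(lo, n, rss) > logy) lo <- lo - w
  lo <- max(lo, SIGMA_FLOOR)
  while (sigmaLogTarget(hi, n, rss) > logy) hi <- hi + w
  for (k in seq_len(1000L)) {
    s1 <- stats::runif(1L, lo, hi)
    if (sigmaLogTarget(s1, n, rss) > logy) return(s1)
    if (s1 < s0) lo <- s1 else hi <- s1
  }
  s0
}

# Split R-hat over a draws-by-chain matrix (each column one chain's
# post-burn draws); each chain is split in half.
splitRhat <- function(draws, chain) {
  halves <- list()
  for (c in unique(chain)) {
    v <- draws[chain == c]
    m <- length(v) %/% 2L
    halves <- c(halves, list(v[seq_len(m)], v[(m + 1L):(2L * m)]))
  }
  m <- length(halves[[1L]])
  means <- vapply(halves, mean, 1)
  vars <- vapply(halves, stats::var, 1)
  W <- mean(vars)
  B <- m * stats::var(means)
  varPlus <- (m - 1) / m * W + B / m
  sqrt(varPlus / W)
}

#' Fit the Bayesian covariance-tracking model
#'
#' Fits the linear tracking model (see [trackingModelSpec()]) by MCMC.
#' Because the Gaussian likelihood admits conjugate updates, the sampler
#' is a Gibbs scheme: `(intercept, slope)` are drawn jointly from their
#' exact bivariate-normal full conditional given `sigma`, and `sigma` is
#' drawn by slice sampling from its full conditional under the HalfNormal
#' prior. All updates run on six precomputed sufficient statistics, so the
#' per-iteration cost is independent of the data size. Post-burn draws
#' from all chains are pooled; a split R-hat above 1.01 on the slope
#' triggers a warning.
#'
#' With standard-normal priors and thousands of observations the posterior
#' mode is close to the maximum-likelihood (ordinary least squares)
#' estimate, which the tests exploit as an independent oracle.
#'
#' @param x standardized TVC estimates over the common mask.
#' @param y standardized ground-truth covariance over the same mask.
#' @param spec a [TrackingModelSpec].
#' @return A [PosteriorFit].
#' @examples
#' x <- rnorm(200); y <- 0.5 * x + rnorm(200)
#' fit <- fitTrackingModel(scale(x)[, 1], scale(y)[, 1],
#'                         trackingModelSpec(draws = 600, burn = 100,
#'                                           seed = 1))
#' posteriorSummary(fit)$mean
#' @export
fitTrackingModel <- function(x, y, spec = trackingModelSpec()) {
  n <- length(x)
  if (length(y) != n) stop("'x' and 'y' must have the same length")
  if (n < 10L) stop("need at least 10 observations")
  if (abs(mean(x)) > 0.2 || abs(mean(y)) > 0.2 ||
      abs(stats::sd(x) - 1) > 0.5 || abs(stats::sd(y) - 1) > 0.5)
    warning("'x' and 'y' should be standardized (mean 0, sd 1)")
  validObject(spec)

  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); syy <- sum(y * y); sxy <- sum(x * y)
  nKeep <- spec@draws - spec@burn
  S <- nKeep * spec@chains
  draws <- matrix(NA_real_, S, 3L,
                  dimnames = list(NULL, c("intercept", "slope", "sigma")))
  chainId <- integer(S)

  runChains <- function() {
    row <- 0L
    for (c in seq_len(spec@chains)) {
      # mildly overdispersed initial values, one stream for everything
      a <- stats::rnorm(1L, 0, 0.5)
      b <- stats::rnorm(1L, 0, 0.5)
      sig <- abs(stats::rnorm(1L, 1, 0.25)) + 0.05
      for (it in seq_len(spec@draws)) {
        # (a, b) | sigma: bivariate-normal conjugate update
        is2 <- 1 / (sig * sig)
        p11 <- 1 + n * is2
        p12 <- sx * is2
        p22 <- 1 + sxx * is2
        det <- p11 * p22 - p12 * p12
        r1 <- sy * is2; r2 <- sxy * is2
        m1 <- (p22 * r1 - p12 * r2) / det
        m2 <- (p11 * r2 - p12 * r1) / det
        # Cholesky of the 2x2 posterior covariance P^{-1}
        c11 <- p22 / det; c12 <- -p12 / det; c22 <- p11 / det
        l11 <- sqrt(c11)
        l21 <- c12 / l11
        l22 <- sqrt(c22 - l21 * l21)
        z <- stats::rnorm(2L)
        a <- m1 + l11 * z[1L]
        b <- m2 + l21 * z[1L] + l22 * z[2L]
        # sigma | (a, b): slice sample; RSS from sufficient statistics
        rss <- max(0, syy + n * a * a + b * b * sxx + 2 * a * b * sx -
                     2 * a * sy - 2 * b * sxy)
        sig <- sliceSigma(sig, n, rss, w = 0.1 * sig + 1e-3)
        if (it > spec@burn) {
          row <- row + 1L
          draws[row, 1L] <<- a
          draws[row, 2L] <<- b
          draws[row, 3L] <<- sig
          chainId[row] <<- c
        }
      }
    }
  }
  withSeed(spec@seed, runChains())

  diag <- list(
    rhatIntercept = splitRhat(draws[, "intercept"], chainId),
    rhatSlope = splitRhat(draws[, "slope"], chainId),
    rhatSigma = splitRhat(draws[, "sigma"], chainId)
  )
  if (spec@chains > 1L && is.finite(diag$rhatSlope) &&
      diag$rhatSlope > 1.01)
    warning(sprintf("slope split R-hat = %.3f > 1.01; inspect convergence",
                    diag$rhatSlope))
  new("PosteriorFit", draws = draws, chain = chainId, x = as.numeric(x),
      y = as.numeric(y), spec = spec, diagnostics = diag)
}

#' Pointwise log-likelihood matrix of a fit
#'
#' The S x N matrix of log p(y_i | draw_s). Intended for small problems
#' (oracle tests, inspection); [waic()] accumulates the same quantities in
#' C++ without materializing this matrix.
#'
#' @param fit a [PosteriorFit].
#' @return Numeric S x N matrix.
#' @export
pointwiseLogLik <- function(fit) {
  stopifnot(is(fit, "PosteriorFit"))
  d <- fit@draws
  mu <- cbind(1, fit@x) %*% t(d[, c("intercept", "slope")])  # N x S
  t(stats::dnorm(fit@y, mean = mu,
                 sd = rep(d[, "sigma"], each = length(fit@y)), log = TRUE))
}

#' Watanabe-Akaike information criterion of a tracking-model fit
#'
#' WAIC on the deviance scale: with pointwise log predictive density
#' `lppd_i = log mean_s p(y_i | draw_s)` and effective-parameter penalty
#' `p_i = var_s log p(y_i | draw_s)`,
#' `waic = -2 * sum(lppd_i - p_i)`. The standard error is
#' `sqrt(N * var(-2 (lppd_i - p_i)))` over the pointwise contributions.
#' Lower is better. Log-sum-exp guards against underflow.
#'
#' @param fit a [PosteriorFit].
#' @return List with `waic`, `se`, and the pointwise `lppd` and `pWaic`
#'   vectors.
#' @export
waic <- function(fit) {
  stopifnot(is(fit, "PosteriorFit"))
  d <- fit@draws
  cpp_waic(d[, "intercept"], d[, "slope"], d[, "sigma"], fit@x, fit@y)
}

#' Summaries of the slope posterior
#'
#' Mode (Gaussian-kernel density argmax, Silverman bandwidth, 512-point
#' grid), mean, central 95% credible interval, and the fraction of slope
#' draws above zero.
#'
#' @param fit a [PosteriorFit].
#' @param parameter which parameter to summarize (default `"slope"`).
#' @return List with `mode`, `mean`, `ci` (length 2), `fracPositive`.
#' @export
posteriorSummary <- function(fit, parameter = c("slope", "intercept",
                                                "sigma")) {
  stopifnot(is(fit, "PosteriorFit"))
  parameter <- match.arg(parameter)
  v <- fit@draws[, parameter]
  if (length(v) < 100L) stop("need at least 100 post-burn draws")
  dens <- stats::density(v, bw = "nrd0", n = 512L)
  list(mode = dens$x[which.max(dens$y)],
       mean = mean(v),
       ci = unname(stats::quantile(v, c(0.025, 0.975))),
       fracPositive = mean(v > 0))
}
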