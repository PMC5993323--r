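#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' BivariatePair: two aligned simulated time series
#'
#' Container for a pair of time series of common length `T`, stored as a
#' `T x 2` matrix, together with the generation metadata (simulation id,
#' seed, model parameters) needed to reproduce it.
#'
#' @slot values numeric `T x 2` matrix of signal values.
#' @slot meta named list of generation parameters.
#'
#' @exportClass BivariatePair
setClass("BivariatePair",
  slots = c(values = "matrix", meta = "list"),
  prototype = prototype(values = matrix(0, 2, 2), meta = list())
)

setValidity("BivariatePair", function(object) {
  v <- object@values
  if (!is.numeric(v) || ncol(v) != 2L)
    return("'values' must be a numeric matrix with exactly 2 columns")
  if (nrow(v) < 2L)
    return("a pair must contain at least 2 time points")
  if (!all(is.finite(v)))
    return("'values' must be finite")
  TRUE
})

#' CovarianceTrack: ground-truth time-varying covariance
#'
#' The per-time-point covariance parameter r_t used to generate a
#' [BivariatePair], plus the parameters of the process that produced it.
#' With unit variances, r_t is both the covariance and the correlation of
#' the generating bivariate Gaussian, so every entry must lie strictly
#' inside (-1, 1) for the covariance matrix to be positive definite.
#'
#' @slot r numeric vector of per-time-point covariance parameters.
#' @slot muR numeric, innovation mean of the covariance process.
#' @slot sigmaR numeric, innovation standard deviation.
#' @slot alphaR numeric in `[0, 1)`, lag-1 autoregression of the covariance.
#' @slot clampBound numeric in (0, 1], bound into which r_t is clamped.
#'
#' @exportClass CovarianceTrack
setClass("CovarianceTrack",
  slots = c(r = "numeric", muR = "numeric", sigmaR = "numeric",
            alphaR = "numeric", clampBound = "numeric"),
  prototype = prototype(r = numeric(0), muR = 0, sigmaR = 0.1,
                        alphaR = 0, clampBound = 0.999)
)

setValidity("CovarianceTrack", function(object) {
  if (length(object@r) && max(abs(object@r)) >= 1)
    return("all covariance values must satisfy |r_t| < 1")
  if (length(object@clampBound) != 1L || object@clampBound <= 0 ||
      object@clampBound > 1)
    return("'clampBound' must lie in (0, 1]")
  if (length(object@alphaR) != 1L || object@alphaR < 0 || object@alphaR >= 1)
    return("'alphaR' must lie in [0, 1)")
  TRUE
})

setClassUnion("CovarianceTrackOrNULL", c("CovarianceTrack", "NULL"))

#' StateSchedule: piecewise-constant covariance state layout
#'
#' Tiling of `[1, T]` into contiguous segments, each with a duration drawn
#' from a duration set `L` and a state mean drawn from a mean set `M`.
#' The final segment may be truncated at `T`.
#'
#' @slot segments data.frame with columns `start` (1-based), `duration`,
#'   and `mean`; segments tile `[1, T]` with no gaps or overlaps.
#' @slot stateMeans numeric, the set `M` of possible state means.
#' @slot durationSet integer, the set `L` of possible durations.
#'
#' @exportClass StateSchedule
setClass("StateSchedule",
  slots = c(segments = "data.frame", stateMeans = "numeric",
            durationSet = "integer")
)

setValidity("StateSchedule", function(object) {
  seg <- object@segments
  if (!all(c("start", "duration", "mean") %in% names(seg)))
    return("'segments' needs columns start, duration, mean")
  if (nrow(seg)) {
    expected <- cumsum(c(1, seg$duration[-nrow(seg)]))
    if (!all(seg$start == expected))
      return("segments must tile the series with no gaps or overlaps")
    if (!all(seg$mean %in% object@stateMeans))
      return("every segment mean must belong to the state-mean set")
    # all but the (possibly truncated) last segment must use listed durations
    if (nrow(seg) > 1L &&
        !all(seg$duration[-nrow(seg)] %in% object@durationSet))
      return("every non-final duration must belong to the duration set")
  }
  TRUE
})

setClassUnion("StateScheduleOrNULL", c("StateSchedule", "NULL"))

#' HRFKernel: sampled canonical haemodynamic response
#'
#' A double-gamma haemodynamic response function sampled at the repetition
#' time, normalized to unit sum over its samples (the convention of the
#' canonical SPM implementation), multiplied by `amplitude`, and padded
#' with three trailing zeros (20 samples at TR = 2 s).
#'
#' @slot samples numeric vector of response amplitudes per TR (length 20
#'   at TR = 2 s: 17 sampled points + 3 zero pads).
#' @slot tr numeric, repetition time in seconds.
#' @slot amplitude numeric, the sum of the scaled kernel (default 10).
#'
#' @exportClass HRFKernel
setClass("HRFKernel",
  slots = c(samples = "numeric", tr = "numeric", amplitude = "numeric")
)

setValidity("HRFKernel", function(object) {
  n <- length(object@samples)
  if (n < 5L)
    return("'samples' must contain the sampled HRF plus 3 zero pads")
  if (any(object@samples[(n - 2L):n] != 0))
    return("the last 3 samples must be exactly zero")
  if (abs(sum(object@samples) - object@amplitude) > 1e-8)
    return("the kernel must sum to 'amplitude' (unit-sum HRF x amplitude)")
  if (object@tr <= 0) return("'tr' must be positive")
  TRUE
})

#' SimulatedDataset: a generated benchmark dataset
#'
#' One simulated dataset: the pair of time series, the ground-truth
#' covariance track (absent for the constant-covariance regime), the mean
#' track (all zeros except for the HRF regime), and the state schedule
#' (state-switching regime only).
#'
#' @slot pair a [BivariatePair].
#' @slot truth a [CovarianceTrack] or `NULL`.
#' @slot meanTrack numeric length-T vector added to both series' means.
#' @slot schedule a [StateSchedule] or `NULL`.
#' @slot simId character simulation label (e.g. `"sim1"`).
#'
#' @exportClass SimulatedDataset
setClass("SimulatedDataset",
  slots = c(pair = "BivariatePair", truth = "CovarianceTrackOrNULL",
            meanTrack = "numeric", schedule = "StateScheduleOrNULL",
            simId = "character")
)

setValidity("SimulatedDataset", function(object) {
  T <- nrow(object@pair@values)
  if (length(object@meanTrack) != T)
    return("'meanTrack' must share the pair's length")
  if (!is.null(object@truth) && length(object@truth@r) != T)
    return("'truth' must share the pair's length")
  TRUE
})

#' TVCSeries: one method's time-varying connectivity estimate
#'
#' Per-time-point connectivity estimates from one TVC method, with a
#' validity mask. Windowed methods cannot estimate the edges of the series,
#' so their masks are `FALSE` there; estimates are only required to be
#' finite where the mask is `TRUE`.
#'
#' @slot estimate numeric length-T vector (correlation-scale for SW/TSW/SD/JC,
#'   product-scale for MTD, possibly Fisher-transformed or standardized).
#' @slot valid logical length-T validity mask.
#' @slot method character method label.
#' @slot params named list of method parameters (window length, taper
#'   variance, smoothing length, post-processing flags, ...).
#'
#' @exportClass TVCSeries
setClass("TVCSeries",
  slots = c(estimate = "numeric", valid = "logical", method = "character",
            params = "list"),
  prototype = prototype(params = list())
)

setValidity("TVCSeries", function(object) {
  if (length(object@estimate) != length(object@valid))
    return("'estimate' and 'valid' must have the same length")
  if (any(!is.finite(object@estimate[object@valid])))
    return("estimates must be finite wherever 'valid' is TRUE")
  TRUE
})

#' WindowSpec: sliding-window parameters
#'
#' Window length (odd, so the estimate can be assigned to the window's
#' centre time point) and, for the tapered variant, the variance of the
#' Gaussian taper in squared time points.
#'
#' @slot length odd positive integer window length.
#' @slot taperVariance positive numeric taper variance, or `NULL` for an
#'   untapered window.
#'
#' @exportClass WindowSpec
setClass("WindowSpec",
  slots = c(length = "integer", taperVariance = "numericOrNULL"),
  prototype = prototype(length = 29L, taperVariance = NULL)
)

setValidity("WindowSpec", function(object) {
  if (length(object@length) != 1L || object@length < 3L)
    return("window 'length' must be a single integer >= 3")
  if (object@length %% 2L == 0L)
    return("window 'length' must be odd so each window has a centre point")
  if (!is.null(object@taperVariance) && object@taperVariance <= 0)
    return("'taperVariance' must be positive when present")
  TRUE
})

#' TrackingModelSpec: sampler settings for the tracking model
#'
#' Settings for the Bayesian linear model that regresses the ground-truth
#' covariance on a method's standardized estimate: intercept ~ N(0,1),
#' slope ~ N(0,1), noise sd ~ HalfNormal(0,1).
#'
#' @slot draws integer, MCMC draws per chain (default 5500).
#' @slot burn integer, initial draws discarded per chain (default 500).
#' @slot chains integer, number of chains (default 2).
#' @slot seed integer or NULL, sampler seed.
#'
#' @exportClass TrackingModelSpec
setClass("TrackingModelSpec",
  slots = c(draws = "integer", burn = "integer", chains = "integer",
            seed = "numericOrNULL"),
  prototype = prototype(draws = 5500L, burn = 500L, chains = 2L, seed = NULL)
)

setValidity("TrackingModelSpec", function(object) {
  if (object@draws <= object@burn)
    return("'draws' must exceed 'burn'")
  if (object@chains < 1L) return("'chains' must be >= 1")
  TRUE
})

#' PosteriorFit: MCMC draws for the tracking model
#'
#' Pooled post-burn posterior draws for the tracking model's intercept,
#' slope, and noise sd, together with the (standardized) data so that
#' pointwise log-likelihoods and WAIC can be recomputed on demand.
#'
#' @slot draws numeric S x 3 matrix with columns `intercept`, `slope`,
#'   `sigma` (post-burn, pooled over chains).
#' @slot chain integer length-S chain index for each draw.
#' @slot x numeric predictor vector (standardized TVC estimates).
#' @slot y numeric response vector (standardized r_t).
#' @slot spec the [TrackingModelSpec] used.
#' @slot diagnostics list with convergence diagnostics (split R-hat).
#'
#' @exportClass PosteriorFit
setClass("PosteriorFit",
  slots = c(draws = "matrix", chain = "integer", x = "numeric",
            y = "numeric", spec = "TrackingModelSpec", diagnostics = "list")
)

setValidity("PosteriorFit", function(object) {
  if (!identical(colnames(object@draws), c("intercept", "slope", "sigma")))
    return("'draws' must have columns intercept, slope, sigma")
  if (any(object@draws[, "sigma"] <= 0))
    return("all noise-sd draws must be positive")
  if (length(object@x) != length(object@y))
    return("'x' and 'y' must have the same length")
  if (length(object@chain) != nrow(object@draws))
    return("'chain' must index every draw")
  TRUE
})

#' BenchmarkConfig: full benchmark configuration
#'
#' The simulations to run, their parameter grids, the series length, the
#' method set, the MCMC settings, and the master seed from which every
#' per-condition seed is derived.
#'
#' @slot simulations integer subset of 1:4.
#' @slot tLength integer series length (default 10000).
#' @slot sim2Grid data.frame with columns `alpha`, `sigmaR`.
#' @slot sim3Alphas numeric vector of covariance autocorrelations.
#' @slot sim4Conditions character subset of `c("fast", "slow")`.
#' @slot sim4SigmaR numeric, Sim-4 within-state noise sd.
#' @slot methods character vector of registered method names.
#' @slot mcmc a [TrackingModelSpec].
#' @slot masterSeed numeric master seed.
#'
#' @exportClass BenchmarkConfig
setClass("BenchmarkConfig",
  slots = c(simulations = "integer", tLength = "integer",
            sim2Grid = "data.frame", sim3Alphas = "numeric",
            sim4Conditions = "character", sim4SigmaR = "numeric",
            methods = "character", mcmc = "TrackingModelSpec",
            masterSeed = "numeric")
)

setValidity("BenchmarkConfig", function(object) {
  if (!all(object@simulations %in% 1:4))
    return("'simulations' must be a subset of 1:4")
  if (object@tLength < 100L)
    return("'tLength' must be at least 100")
  if (2L %in% object@simulations && nrow(object@sim2Grid) == 0L)
    return("Sim-2 grid is empty")
  if (!all(object@sim4Conditions %in% c("fast", "slow")))
    return("'sim4Conditions' must be a subset of c('fast','slow')")
  if (length(object@methods) < 1L)
    return("at least one method is required")
  TRUE
})

#' BenchmarkReport: results of a full benchmark run
#'
#' Per-condition model comparisons and posterior summaries (Sims 2-4), the
#' method-similarity matrix (Sim 1), a config echo, per-condition seeds,
#' and convergence diagnostics.
#'
#' @slot version character routine version tag.
#' @slot config the [BenchmarkConfig] that produced the report.
#' @slot similarity similarity matrix from Sim 1 (or NULL).
#' @slot conditions named list, one entry per Sim 2-4 condition, each with
#'   elements `comparison` (data.frame), `posteriors` (data.frame), `seed`,
#'   and `failures`.
#'
#' @exportClass BenchmarkReport
setClass("BenchmarkReport",
  slots = c(version = "character", config = "BenchmarkConfig",
            similarity = "ANY", conditions = "list")
)
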