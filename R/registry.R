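.registry <- new.env(parent = emptyenv())

# Fixed 100-point AR(1) fixture used to smoke-test method contracts.
contractFixture <- function() {
  pairValues(simulateSim1(tLength = 100L, seed = 987L))
}

normalizeMethodResult <- function(res, tLen, name) {
  if (is(res, "TVCSeries")) {
    est <- res@estimate; valid <- res@valid
  } else if (is.list(res) && all(c("estimate", "valid") %in% names(res))) {
    est <- as.numeric(res$estimate); valid <- as.logical(res$valid)
  } else {
    stop(sprintf(
      "method '%s' violated the contract: must return a TVCSeries or a list with 'estimate' and 'valid'",
      name))
  }
  if (length(est) != tLen)
    stop(sprintf("method '%s' violated the contract: estimate length %d != %d",
                 name, length(est), tLen))
  if (length(valid) != tLen || anyNA(valid))
    stop(sprintf("method '%s' violated the contract: 'valid' must be a complete logical mask",
                 name))
  if (any(!is.finite(est[valid])))
    stop(sprintf("method '%s' violated the contract: non-finite estimates at valid points",
                 name))
  newTVCSeries(est, valid, name,
               if (is(res, "TVCSeries")) res@params else list())
}

#' Register a TVC method with the benchmark
#'
#' A method is a function taking a `T x 2` numeric matrix (columns = the
#' two time series) plus a parameter list, returning either a [TVCSeries]
#' or a list with elements `estimate` (length-T numeric) and `valid`
#' (length-T logical). Registration smoke-tests the function on a fixed
#' 100-point AR(1) fixture and rejects it with the failing check named if
#' the contract is violated. Registered methods run alongside the
#' built-ins in [runBenchmark()].
#'
#' @param name unique method name.
#' @param fn the method function `function(values, params)`.
#' @param params named list of parameters passed to `fn`.
#' @param correlationScale logical: are the raw estimates correlations in
#'   `[-1, 1]`? If `TRUE` (default) the benchmark Fisher-transforms the
#'   estimates before model fitting, as it does for SW/TSW/SD/JC but not
#'   for the product-scale MTD.
#' @param overwrite allow replacing an existing entry.
#' @return The method name, invisibly.
#' @examples
#' registerMethod("JC-copy", function(values, params)
#'   jackknifeCorrelation(values), overwrite = TRUE)
#' "JC-copy" %in% registeredMethods()
#' @export
registerMethod <- function(name, fn, params = list(),
                           correlationScale = TRUE, overwrite = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!overwrite && exists(name, envir = .registry, inherits = FALSE))
    stop(sprintf("method '%s' is already registered", name))
  stopifnot(is.function(fn))
  fixture <- contractFixture()
  res <- fn(fixture, params)
  series <- normalizeMethodResult(res, nrow(fixture), name)
  if (correlationScale) {
    raw <- series@estimate[series@valid]
    if (length(raw) && (min(raw) < -1 || max(raw) > 1))
      stop(sprintf(
        "method '%s' violated the contract: correlation-scale estimates outside [-1, 1]",
        name))
  }
  assign(name, list(fn = fn, params = params,
                    correlationScale = correlationScale),
         envir = .registry)
  invisible(name)
}

#' List registered method names
#' @return Character vector of registered method names.
#' @export
registeredMethods <- function() sort(ls(.registry))

#' Names of the built-in benchmark methods
#'
#' The method set evaluated by default: sliding windows of length 15 and
#' 29, Gaussian-tapered windows of the same lengths (taper sd 10 time
#' points), spatial distance, jackknife correlation, and MTD with a
#' 7-point smoothing window.
#' @return Character vector of the seven built-in method names.
#' @export
defaultMethods <- function() {
  c("SW-15", "SW-29", "TSW-15", "TSW-29", "SD", "JC", "MTD-7")
}

#' Run one registered method on a pair of series
#'
#' @param name a registered method name.
#' @param pair a [BivariatePair], [SimulatedDataset], or T x 2 matrix.
#' @return A [TVCSeries].
#' @export
runRegisteredMethod <- function(name, pair) {
  if (!exists(name, envir = .registry, inherits = FALSE))
    stop(sprintf("method '%s' is not registered", name))
  entry <- get(name, envir = .registry, inherits = FALSE)
  v <- asPairMatrix(pair)
  normalizeMethodResult(entry$fn(v, entry$params), nrow(v), name)
}

methodEntry <- function(name) {
  if (!exists(name, envir = .registry, inherits = FALSE))
    stop(sprintf("method '%s' is not registered", name))
  get(name, envir = .registry, inherits = FALSE)
}

registerBuiltins <- function() {
  reg <- function(name, fn, params = list(), corr = TRUE)
    assign(name, list(fn = fn, params = params, correlationScale = corr),
           envir = .registry)
  reg("SW-15", function(v, p) slidingWindow(v, windowSpec(15L)))
  reg("SW-29", function(v, p) slidingWindow(v, windowSpec(29L)))
  reg("TSW-15", function(v, p) taperedSlidingWindow(v, windowSpec(15L, 100)))
  reg("TSW-29", function(v, p) taperedSlidingWindow(v, windowSpec(29L, 100)))
  reg("SD", function(v, p) spatialDistanceTvc(v, mode = "bivariate"))
  reg("JC", function(v, p) jackknifeCorrelation(v))
  reg("MTD-7", function(v, p) mtd(v, smoothWindow = 7L), corr = FALSE)
}
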