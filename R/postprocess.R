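#' Fisher (atanh) transform of a connectivity series
#'
#' Applies the variance-stabilizing `atanh` transform elementwise over the
#' valid points of a correlation-scale series. Estimates are clamped to
#' `|r| <= 1 - 1e-12` first so exact +/-1 values stay finite. Product-scale
#' series (MTD) are not correlations and are rejected.
#'
#' @param series a [TVCSeries] from a correlation-scale method.
#' @return A [TVCSeries] with `params$fisher = TRUE`.
#' @export
fisherTransform <- function(series) {
  stopifnot(is(series, "TVCSeries"))
  if (identical(series@params$scale, "product"))
    stop("Fisher transform is undefined for product-scale (MTD) series")
  if (isTRUE(series@params$fisher))
    return(series)
  est <- series@estimate
  idx <- series@valid
  est[idx] <- atanh(pmin(pmax(est[idx], -1 + 1e-12), 1 - 1e-12))
  out <- series
  out@estimate <- est
  out@params$fisher <- TRUE
  validObject(out)
  out
}

#' Standardize a connectivity series
#'
#' Centres and scales the valid estimates to zero mean and unit standard
#' deviation (population convention, dividing by N). When `mask` is given,
#' the moments are computed over `mask & valid` only - this is how series
#' are standardized over the common valid mask before model fitting - while
#' all valid points are transformed. Standardizing twice is a no-op.
#'
#' @param series a [TVCSeries].
#' @param mask optional logical mask restricting the moment computation.
#' @return A standardized [TVCSeries].
#' @export
standardizeSeries <- function(series, mask = NULL) {
  stopifnot(is(series, "TVCSeries"))
  idx <- series@valid
  if (!is.null(mask)) {
    if (length(mask) != length(idx)) stop("'mask' has the wrong length")
    idx <- idx & mask
  }
  if (!any(idx)) stop("no valid points to standardize over")
  v <- series@estimate[idx]
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s == 0) stop("constant series cannot be standardized")
  out <- series
  out@estimate[out@valid] <- (out@estimate[out@valid] - m) / s
  out@params$standardized <- TRUE
  out
}

# Standardize a plain numeric vector with the same population convention.
standardizeVector <- function(v) {
  s <- sqrt(mean((v - mean(v))^2))
  if (s == 0) stop("constant vector cannot be standardized")
  (v - mean(v)) / s
}

#' Common valid-time-point mask
#'
#' Logical AND of the validity masks of several connectivity series: the
#' time points every method can estimate. With the benchmark's default
#' methods at T = 10000 the longest window (29) dominates and 9972 points
#' remain.
#'
#' @param seriesList a list of [TVCSeries] over the same time base.
#' @return Logical length-T mask.
#' @export
commonValidMask <- function(seriesList) {
  stopifnot(length(seriesList) >= 1L)
  masks <- lapply(seriesList, function(s) {
    stopifnot(is(s, "TVCSeries"))
    s@valid
  })
  lens <- vapply(masks, length, 1L)
  if (length(unique(lens)) != 1L)
    stop("all series must share the same length")
  mask <- Reduce(`&`, masks)
  if (!any(mask)) stop("the common valid mask is empty")
  mask
}
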