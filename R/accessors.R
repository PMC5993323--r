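#' Accessors for tvcbench classes
#'
#' Small accessor generics so user code never touches slots directly:
#' `nTime()` (series length), `pairValues()` (T x 2 matrix), `truthTrack()`
#' (ground-truth r_t vector or NULL), `tvcEstimate()` / `validMask()`
#' (a method's estimates and validity), and `posteriorDraws()` (pooled
#' post-burn MCMC draws).
#'
#' @param object an object of the documented class.
#' @return See each method's description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nTime", function(object) standardGeneric("nTime"))

#' @rdname accessors
#' @export
setMethod("nTime", "BivariatePair", function(object) nrow(object@values))

#' @rdname accessors
#' @export
setMethod("nTime", "SimulatedDataset", function(object) nTime(object@pair))

#' @rdname accessors
#' @export
setMethod("nTime", "TVCSeries", function(object) length(object@estimate))

#' @rdname accessors
#' @export
setGeneric("pairValues", function(object) standardGeneric("pairValues"))

#' @rdname accessors
#' @export
setMethod("pairValues", "BivariatePair", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("pairValues", "SimulatedDataset",
          function(object) object@pair@values)

#' @rdname accessors
#' @export
setGeneric("truthTrack", function(object) standardGeneric("truthTrack"))

#' @rdname accessors
#' @export
setMethod("truthTrack", "CovarianceTrack", function(object) object@r)

#' @rdname accessors
#' @export
setMethod("truthTrack", "SimulatedDataset", function(object) {
  if (is.null(object@truth)) NULL else object@truth@r
})

#' @rdname accessors
#' @export
setGeneric("tvcEstimate", function(object) standardGeneric("tvcEstimate"))

#' @rdname accessors
#' @export
setMethod("tvcEstimate", "TVCSeries", function(object) object@estimate)

#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))

#' @rdname accessors
#' @export
setMethod("validMask", "TVCSeries", function(object) object@valid)

#' @rdname accessors
#' @export
setGeneric("methodLabel", function(object) standardGeneric("methodLabel"))

#' @rdname accessors
#' @export
setMethod("methodLabel", "TVCSeries", function(object) object@method)

#' @rdname accessors
#' @export
setGeneric("posteriorDraws", function(object) standardGeneric("posteriorDraws"))

#' @rdname accessors
#' @export
setMethod("posteriorDraws", "PosteriorFit", function(object) object@draws)

#' @rdname accessors
#' @export
setGeneric("hrfSamples", function(object) standardGeneric("hrfSamples"))

#' @rdname accessors
#' @export
setMethod("hrfSamples", "HRFKernel", function(object) object@samples)

#' @rdname accessors
#' @export
setGeneric("scheduleSegments",
           function(object) standardGeneric("scheduleSegments"))

#' @rdname accessors
#' @export
setMethod("scheduleSegments", "StateSchedule",
          function(object) object@segments)

setMethod("show", "BivariatePair", function(object) {
  cat("BivariatePair with", nTime(object), "time points\n")
  m <- object@meta
  if (length(m))
    cat("  meta:", paste(names(m), unlist(lapply(m, format)),
                         sep = "=", collapse = ", "), "\n")
})

setMethod("show", "CovarianceTrack", function(object) {
  cat(sprintf(
    "CovarianceTrack of length %d (muR=%g, sigmaR=%g, alphaR=%g, clamp=%g)\n",
    length(object@r), object@muR, object@sigmaR, object@alphaR,
    object@clampBound))
  if (length(object@r))
    cat(sprintf("  range [%.3f, %.3f], mean %.3f\n",
                min(object@r), max(object@r), mean(object@r)))
})

setMethod("show", "StateSchedule", function(object) {
  cat(sprintf("StateSchedule with %d segments; M={%s}, L={%s}\n",
              nrow(object@segments),
              paste(object@stateMeans, collapse = ","),
              paste(object@durationSet, collapse = ",")))
})

setMethod("show", "HRFKernel", function(object) {
  cat(sprintf("HRFKernel: %d samples at TR=%gs, unit-sum HRF x %g (peak %.2f)\n",
              length(object@samples), object@tr, object@amplitude,
              max(object@samples)))
})

setMethod("show", "SimulatedDataset", function(object) {
  cat(sprintf("SimulatedDataset '%s': %d time points\n",
              object@simId, nTime(object)))
  if (!is.null(object@truth)) {
    cat("  with ground-truth covariance track\n")
  }
  if (any(object@meanTrack != 0)) cat("  with non-zero mean track\n")
  if (!is.null(object@schedule))
    cat("  with", nrow(object@schedule@segments), "covariance states\n")
})

setMethod("show", "TVCSeries", function(object) {
  cat(sprintf("TVCSeries [%s]: %d time points, %d valid\n",
              object@method, nTime(object), sum(object@valid)))
  if (length(object@params))
    cat("  params:", paste(names(object@params),
                           unlist(lapply(object@params, format)),
                           sep = "=", collapse = ", "), "\n")
})

setMethod("show", "PosteriorFit", function(object) {
  s <- object@draws[, "slope"]
  cat(sprintf(
    "PosteriorFit: %d pooled draws (%d chains), n_obs=%d\n",
    nrow(object@draws), length(unique(object@chain)), length(object@y)))
  cat(sprintf("  slope: mean %.3f, sd %.3f; split-Rhat %.3f\n",
              mean(s), stats::sd(s),
              object@diagnostics$rhatSlope %||% NA_real_))
})

setMethod("show", "BenchmarkConfig", function(object) {
  cat(sprintf("BenchmarkConfig: sims {%s}, T=%d, %d methods, master seed %s\n",
              paste(object@simulations, collapse = ","), object@tLength,
              length(object@methods), format(object@masterSeed)))
})

setMethod("show", "BenchmarkReport", function(object) {
  cat(sprintf("BenchmarkReport (%s): %d conditions%s\n",
              object@version, length(object@conditions),
              if (!is.null(object@similarity)) " + similarity matrix" else ""))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
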