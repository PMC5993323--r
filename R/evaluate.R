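#' Compare tracking-model fits by WAIC
#'
#' Computes WAIC for each method's fit (all fitted to the same response
#' over the same mask), the difference from the best (lowest) WAIC, and
#' returns the table sorted ascending - the best-fitting method first with
#' `deltaWaic = 0`.
#'
#' @param fits named list of [PosteriorFit] objects (>= 2), one per method.
#' @return `data.frame` with columns `method`, `waic`, `waicSE`,
#'   `deltaWaic`, sorted by `waic`.
#' @export
compareModels <- function(fits) {
  if (length(fits) < 2L) stop("need at least 2 fits to compare")
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    stop("'fits' must be a named list")
  y0 <- fits[[1L]]@y
  for (f in fits) {
    if (length(f@y) != length(y0) || max(abs(f@y - y0)) > 1e-8)
      stop("mask mismatch: all fits must share the same response")
  }
  w <- lapply(fits, waic)
  out <- data.frame(method = names(fits),
                    waic = vapply(w, function(z) z$waic, 1),
                    waicSE = vapply(w, function(z) z$se, 1),
                    row.names = NULL)
  out$deltaWaic <- out$waic - min(out$waic)
  out <- out[order(out$waic), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise Spearman similarity of connectivity series
#'
#' Spearman rank correlation between every pair of methods' estimates,
#' restricted to a common valid mask. Rank correlation is invariant to
#' monotone rescalings, so Fisher transforms and standardization do not
#' affect it; ties get average ranks.
#'
#' @param seriesList named list of [TVCSeries] over the same time base.
#' @param mask optional logical mask (default: [commonValidMask()] of the
#'   list).
#' @return Symmetric correlation matrix with unit diagonal, dimnames from
#'   the method labels.
#' @export
methodSimilarity <- function(seriesList, mask = NULL) {
  stopifnot(length(seriesList) >= 2L)
  if (is.null(mask)) mask <- commonValidMask(seriesList)
  labels <- names(seriesList)
  if (is.null(labels))
    labels <- vapply(seriesList, methodLabel, "")
  m <- vapply(seriesList, function(s) s@estimate[mask],
              numeric(sum(mask)))
  colnames(m) <- labels
  rho <- stats::cor(m, method = "spearman")
  diag(rho) <- 1
  rho
}
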