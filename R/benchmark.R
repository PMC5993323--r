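ROUTINE_VERSION <- "tvcbench simulation routine V1.0"

#' Construct a benchmark configuration
#'
#' The default configuration mirrors the full benchmark: series of 10000
#' points; the fluctuating-covariance grid of three covariance
#' autocorrelations crossed with three covariance noise levels; the three
#' HRF-mean conditions; the fast and slow state-switching conditions; the
#' seven built-in methods; and the default MCMC settings.
#'
#' The state-switching conditions use a within-state noise sd of 0.1 so
#' that the two states (means 0.2 and 0.6) remain distinguishable from the
#' per-point noise; see the vignette for the calibration rationale.
#'
#' @param simulations integer subset of 1:4 to run.
#' @param tLength series length (default 10000).
#' @param sim2Grid data.frame with columns `alpha`, `sigmaR`.
#' @param sim3Alphas covariance autocorrelations for the HRF regime.
#' @param sim4Conditions subset of `c("fast", "slow")`.
#' @param sim4SigmaR within-state noise sd for the state regime.
#' @param methods registered method names to evaluate.
#' @param mcmc a [TrackingModelSpec].
#' @param masterSeed master seed; every per-condition seed is derived from
#'   it deterministically.
#' @return A [BenchmarkConfig].
#' @export
benchmarkConfig <- function(simulations = 1:4,
                            tLength = 10000L,
                            sim2Grid = expand.grid(
                              alpha = c(0, 0.25, 0.5),
                              sigmaR = c(0.08, 0.1, 0.12)),
                            sim3Alphas = c(0, 0.25, 0.5),
                            sim4Conditions = c("fast", "slow"),
                            sim4SigmaR = 0.1,
                            methods = defaultMethods(),
                            mcmc = trackingModelSpec(),
                            masterSeed = 42) {
  new("BenchmarkConfig", simulations = as.integer(simulations),
      tLength = as.integer(tLength), sim2Grid = sim2Grid,
      sim3Alphas = sim3Alphas, sim4Conditions = sim4Conditions,
      sim4SigmaR = sim4SigmaR, methods = methods, mcmc = mcmc,
      masterSeed = masterSeed)
}

#' Scale a configuration down for quick runs
#'
#' Shrinks the series length and the MCMC draws while preserving the
#' method set and parameter grids; validity masks and window edges are
#' recomputed consistently from the new length.
#'
#' @param config a [BenchmarkConfig].
#' @param tSmall reduced series length (>= 200 and at least the largest
#'   window length).
#' @param drawsSmall reduced draws per chain (optional).
#' @param burnSmall reduced burn-in (default `drawsSmall %/% 11`, the
#'   default draws:burn ratio).
#' @return A reduced [BenchmarkConfig].
#' @export
scaleConfig <- function(config, tSmall, drawsSmall = NULL,
                        burnSmall = NULL) {
  stopifnot(is(config, "BenchmarkConfig"))
  tSmall <- as.integer(tSmall)
  if (tSmall < 200L) stop("'tSmall' must be at least 200")
  maxWin <- 0L
  for (m in config@methods) {
    len <- regmatches(m, regexpr("[0-9]+$", m))
    if (grepl("^T?SW-", m) && length(len))
      maxWin <- max(maxWin, as.integer(len))
  }
  if (maxWin > 0L && tSmall < maxWin)
    stop("'tSmall' is below the largest window length")
  config@tLength <- tSmall
  if (!is.null(drawsSmall)) {
    drawsSmall <- as.integer(drawsSmall)
    if (is.null(burnSmall)) burnSmall <- max(1L, drawsSmall %/% 11L)
    config@mcmc <- trackingModelSpec(draws = drawsSmall,
                                     burn = as.integer(burnSmall),
                                     chains = config@mcmc@chains,
                                     seed = config@mcmc@seed)
  }
  validObject(config)
  config
}

# Deterministic per-condition seed fan-out: a multiplicative hash of the
# master seed and the condition index, kept inside the 32-bit range so
# conditions are independent and reorderable.
conditionSeed <- function(masterSeed, index) {
  m <- 2147483629
  s <- (as.numeric(masterSeed) %% m) * 48271 + as.numeric(index) * 16807
  as.integer(s %% m + 1)
}

# Enumerate the Sim 2-4 conditions of a config, in a stable order.
benchmarkConditions <- function(config) {
  conds <- list()
  if (2L %in% config@simulations) {
    for (i in seq_len(nrow(config@sim2Grid))) {
      a <- config@sim2Grid$alpha[i]; s <- config@sim2Grid$sigmaR[i]
      conds[[length(conds) + 1L]] <-
        list(sim = 2L, alpha = a, sigmaR = s,
             label = sprintf("sim2_alpha%g_sigmaR%g", a, s))
    }
  }
  if (3L %in% config@simulations) {
    for (a in config@sim3Alphas)
      conds[[length(conds) + 1L]] <-
        list(sim = 3L, alpha = a, sigmaR = 0.1,
             label = sprintf("sim3_alpha%g", a))
  }
  if (4L %in% config@simulations) {
    for (cc in config@sim4Conditions)
      conds[[length(conds) + 1L]] <-
        list(sim = 4L, condition = cc, sigmaR = config@sim4SigmaR,
             label = sprintf("sim4_%s", cc))
  }
  conds
}

generateCondition <- function(cond, tLength, seed) {
  switch(as.character(cond$sim),
    "2" = simulateSim2(tLength, alpha = cond$alpha, sigmaR = cond$sigmaR,
                       seed = seed),
    "3" = simulateSim3(tLength, alpha = cond$alpha, sigmaR = cond$sigmaR,
                       seed = seed),
    "4" = simulateSim4(tLength, condition = cond$condition,
                       sigmaR = cond$sigmaR, seed = seed),
    stop("unknown simulation id"))
}

# Run all configured methods on one dataset; failures are captured, not
# fatal. Returns list(series = named list of TVCSeries, failures = named
# character vector of error messages).
runMethods <- function(methods, ds) {
  series <- list(); failures <- character(0)
  v <- pairValues(ds)
  for (m in methods) {
    res <- tryCatch(runRegisteredMethod(m, v), error = function(e) e)
    if (inherits(res, "error")) failures[m] <- conditionMessage(res)
    else series[[m]] <- res
  }
  list(series = series, failures = failures)
}

#' Evaluate every method's covariance tracking on one dataset
#'
#' The per-condition pipeline: run each method, Fisher-transform the
#' correlation-scale estimates, intersect the validity masks, standardize
#' each estimate series and the ground-truth track over the common mask,
#' fit the tracking model per method, and compare by WAIC. Methods that
#' fail at any stage (including degenerate constant estimates) are
#' reported in `failures` rather than aborting the condition.
#'
#' @param ds a [SimulatedDataset] with ground truth.
#' @param methods registered method names.
#' @param mcmc a [TrackingModelSpec]; its seed, when set, is offset per
#'   method so fits are independent but reproducible.
#' @return List with `comparison` (WAIC data.frame), `posteriors`
#'   (per-method slope summaries), `fits`, `mask`, `failures`.
#' @export
evaluateCondition <- function(ds, methods = defaultMethods(),
                              mcmc = trackingModelSpec()) {
  stopifnot(is(ds, "SimulatedDataset"))
  truth <- truthTrack(ds)
  if (is.null(truth))
    stop("dataset has no ground-truth covariance track")
  run <- runMethods(methods, ds)
  series <- run$series; failures <- run$failures
  if (length(series) == 0L) stop("every method failed")
  for (m in names(series)) {
    if (methodEntry(m)$correlationScale)
      series[[m]] <- fisherTransform(series[[m]])
  }
  mask <- commonValidMask(series)
  y <- standardizeVector(truth[mask])
  fits <- list()
  mIdx <- 0L
  for (m in names(series)) {
    mIdx <- mIdx + 1L
    res <- tryCatch({
      std <- standardizeSeries(series[[m]], mask = mask)
      spec <- mcmc
      if (!is.null(spec@seed)) spec@seed <- spec@seed + mIdx
      fitTrackingModel(std@estimate[mask], y, spec)
    }, error = function(e) e)
    if (inherits(res, "error")) failures[m] <- conditionMessage(res)
    else fits[[m]] <- res
  }
  if (length(fits) < 2L)
    stop("fewer than 2 methods produced a fit; cannot compare")
  comparison <- compareModels(fits)
  posteriors <- do.call(rbind, lapply(names(fits), function(m) {
    s <- posteriorSummary(fits[[m]])
    data.frame(method = m, slopeMean = s$mean, slopeMode = s$mode,
               ciLow = s$ci[1L], ciHigh = s$ci[2L],
               fracPositive = s$fracPositive)
  }))
  list(comparison = comparison, posteriors = posteriors, fits = fits,
       mask = mask, failures = failures)
}

#' Run the full benchmark
#'
#' For every configured condition: generate the dataset from the
#' condition's derived seed, run all methods, post-process, fit the
#' tracking model per method and compare by WAIC (the method-similarity
#' matrix for the constant-covariance regime, where there is no varying
#' ground truth to track). The run is deterministic given the master
#' seed; per-method failures are isolated into the report.
#'
#' @param config a [BenchmarkConfig].
#' @param verbose print progress lines (default FALSE).
#' @return A [BenchmarkReport].
#' @examples
#' \donttest{
#' cfg <- scaleConfig(benchmarkConfig(simulations = c(1, 2),
#'   sim2Grid = data.frame(alpha = 0, sigmaR = 0.1), masterSeed = 7),
#'   tSmall = 400, drawsSmall = 500)
#' rep <- runBenchmark(cfg)
#' }
#' @export
runBenchmark <- function(config = benchmarkConfig(), verbose = FALSE) {
  stopifnot(is(config, "BenchmarkConfig"))
  validObject(config)
  missing <- setdiff(config@methods, registeredMethods())
  if (length(missing))
    stop("unregistered methods: ", paste(missing, collapse = ", "))

  similarity <- NULL
  if (1L %in% config@simulations) {
    seed1 <- conditionSeed(config@masterSeed, 0L)
    if (verbose) message("sim1 (seed ", seed1, ")")
    ds <- simulateSim1(config@tLength, seed = seed1)
    run <- runMethods(config@methods, ds)
    if (length(run$series) >= 2L)
      similarity <- methodSimilarity(run$series)
    attr(similarity, "seed") <- seed1
    attr(similarity, "failures") <- run$failures
  }

  conds <- benchmarkConditions(config)
  out <- list()
  for (i in seq_along(conds)) {
    cond <- conds[[i]]
    seed <- conditionSeed(config@masterSeed, i)
    if (verbose) message(cond$label, " (seed ", seed, ")")
    ds <- generateCondition(cond, config@tLength, seed)
    mcmc <- config@mcmc
    mcmc@seed <- conditionSeed(config@masterSeed, 100000L + i)
    ev <- evaluateCondition(ds, config@methods, mcmc)
    out[[cond$label]] <- list(
      condition = cond, seed = seed,
      comparison = ev$comparison, posteriors = ev$posteriors,
      nMask = sum(ev$mask), failures = ev$failures,
      diagnostics = lapply(ev$fits, function(f) f@diagnostics))
  }
  new("BenchmarkReport", version = ROUTINE_VERSION, config = config,
      similarity = similarity, conditions = out)
}
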