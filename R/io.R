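#' Write a simulated dataset to CSV
#'
#' Long-format CSV with columns `t`, `x`, `y`, `r_true`, `mu_t`, `sim_id`
#' (`r_true` is empty for the constant-covariance regime). When the
#' dataset carries a state schedule it is written as a JSON sidecar next
#' to the CSV (`<path>.schedule.json`).
#'
#' @param ds a [SimulatedDataset].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeDataset <- function(ds, path) {
  stopifnot(is(ds, "SimulatedDataset"))
  v <- pairValues(ds)
  truth <- truthTrack(ds)
  df <- data.frame(t = seq_len(nrow(v)), x = v[, 1L], y = v[, 2L],
                   r_true = if (is.null(truth)) NA_real_ else truth,
                   mu_t = ds@meanTrack, sim_id = ds@simId)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(ds@schedule)) {
    jsonlite::write_json(
      list(stateMeans = ds@schedule@stateMeans,
           durationSet = ds@schedule@durationSet,
           segments = ds@schedule@segments),
      paste0(path, ".schedule.json"), auto_unbox = FALSE, digits = NA)
  }
  invisible(path)
}

#' Read an ROI-by-time matrix from CSV/TSV
#'
#' Plain-text input for benchmarking user methods on real data: rows are
#' time points, columns are ROIs, with a header row of ROI labels. The
#' delimiter is inferred from the extension (`.tsv` = tab, otherwise
#' comma).
#'
#' @param path CSV or TSV file.
#' @return Numeric T x R matrix with ROI labels as column names.
#' @export
readRoiMatrix <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("all ROI columns must be numeric")
  m
}

#' Write connectivity series to long-format CSV
#'
#' Columns `t`, `method`, `estimate`, `valid`; one block per series.
#'
#' @param seriesList a (possibly named) list of [TVCSeries].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTvcSeries <- function(seriesList, path) {
  if (is(seriesList, "TVCSeries")) seriesList <- list(seriesList)
  blocks <- lapply(seriesList, function(s) {
    data.frame(t = seq_len(nTime(s)), method = methodLabel(s),
               estimate = s@estimate, valid = s@valid)
  })
  utils::write.csv(do.call(rbind, blocks), path, row.names = FALSE)
  invisible(path)
}

reportToList <- function(report) {
  cfg <- report@config
  list(
    version = report@version,
    config = list(
      simulations = cfg@simulations, tLength = cfg@tLength,
      sim2Grid = cfg@sim2Grid, sim3Alphas = cfg@sim3Alphas,
      sim4Conditions = cfg@sim4Conditions, sim4SigmaR = cfg@sim4SigmaR,
      methods = cfg@methods, masterSeed = cfg@masterSeed,
      mcmc = list(draws = cfg@mcmc@draws, burn = cfg@mcmc@burn,
                  chains = cfg@mcmc@chains)),
    similarity = if (!is.null(report@similarity)) {
      s <- report@similarity
      list(methods = colnames(s), rho = unclass(s[seq_len(nrow(s)), ]),
           seed = attr(s, "seed"))
    },
    conditions = lapply(report@conditions, function(cc) {
      list(condition = cc$condition[setdiff(names(cc$condition), "label")],
           label = cc$condition$label, seed = cc$seed, nMask = cc$nMask,
           comparison = cc$comparison, posteriors = cc$posteriors,
           failures = as.list(cc$failures),
           diagnostics = cc$diagnostics)
    })
  )
}

#' Write a benchmark report bundle
#'
#' Writes `report.json` (config echo, seeds, WAIC tables, posterior
#' summaries, diagnostics, failures), a `tables/` directory of per-
#' condition CSVs with columns `sim`, `params`, `method`, `waic`,
#' `waic_se`, `delta_waic`, `slope_mean`, `slope_mode`, `frac_gt0`, and
#' `tables/similarity.csv` when the similarity matrix is present.
#'
#' @param report a [BenchmarkReport].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeReport <- function(report, dir) {
  stopifnot(is(report, "BenchmarkReport"))
  dir.create(file.path(dir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  jsonlite::write_json(reportToList(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  if (!is.null(report@similarity)) {
    utils::write.csv(as.data.frame(report@similarity),
                     file.path(dir, "tables", "similarity.csv"))
  }
  rows <- lapply(names(report@conditions), function(lab) {
    cc <- report@conditions[[lab]]
    tab <- merge(cc$comparison, cc$posteriors, by = "method", sort = FALSE)
    tab <- tab[order(tab$waic), , drop = FALSE]
    cond <- cc$condition
    out <- data.frame(
      sim = cond$sim,
      params = paste(vapply(
        setdiff(names(cond), c("sim", "label")),
        function(k) sprintf("%s=%s", k, cond[[k]]), ""), collapse = ";"),
      method = tab$method, waic = tab$waic, waic_se = tab$waicSE,
      delta_waic = tab$deltaWaic, slope_mean = tab$slopeMean,
      slope_mode = tab$slopeMode, frac_gt0 = tab$fracPositive)
    utils::write.csv(out, file.path(dir, "tables", paste0(lab, ".csv")),
                     row.names = FALSE)
    out
  })
  if (length(rows))
    utils::write.csv(do.call(rbind, rows),
                     file.path(dir, "tables", "comparisons.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' Read a benchmark configuration from YAML
#'
#' Per-simulation parameter blocks mirroring [benchmarkConfig()]'s
#' arguments: top-level keys `simulations`, `tLength`, `masterSeed`,
#' `methods`, `sim2` (lists `alpha`, `sigmaR`, crossed), `sim3`
#' (`alpha`), `sim4` (`conditions`, `sigmaR`), and `mcmc` (`draws`,
#' `burn`, `chains`). Missing keys fall back to the defaults.
#'
#' @param path YAML file.
#' @return A [BenchmarkConfig].
#' @export
readBenchmarkConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(cfg$simulations)) args$simulations <- as.integer(cfg$simulations)
  if (!is.null(cfg$tLength)) args$tLength <- cfg$tLength
  if (!is.null(cfg$masterSeed)) args$masterSeed <- cfg$masterSeed
  if (!is.null(cfg$methods)) args$methods <- as.character(cfg$methods)
  if (!is.null(cfg$sim2))
    args$sim2Grid <- expand.grid(alpha = cfg$sim2$alpha,
                                 sigmaR = cfg$sim2$sigmaR)
  if (!is.null(cfg$sim3)) args$sim3Alphas <- cfg$sim3$alpha
  if (!is.null(cfg$sim4)) {
    if (!is.null(cfg$sim4$conditions))
      args$sim4Conditions <- cfg$sim4$conditions
    if (!is.null(cfg$sim4$sigmaR)) args$sim4SigmaR <- cfg$sim4$sigmaR
  }
  if (!is.null(cfg$mcmc))
    args$mcmc <- trackingModelSpec(
      draws = cfg$mcmc$draws %||% 5500L,
      burn = cfg$mcmc$burn %||% 500L,
      chains = cfg$mcmc$chains %||% 2L,
      seed = cfg$mcmc$seed)
  do.call(benchmarkConfig, args)
}
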