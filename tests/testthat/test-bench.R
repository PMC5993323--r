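quickMcmc <- function(seed = NULL) {
  trackingModelSpec(draws = 550L, burn = 50L, chains = 2L, seed = seed)
}

test_that("a re-registered copy of a built-in reproduces it exactly", {
  registerMethod("JC-copy", function(values, params)
    jackknifeCorrelation(values), overwrite = TRUE)
  ds <- simulateSim2(300L, seed = 1)
  expect_equal(tvcEstimate(runRegisteredMethod("JC-copy", ds)),
               tvcEstimate(runRegisteredMethod("JC", ds)))
  expect_true("JC-copy" %in% registeredMethods())
})

test_that("contract violations are rejected with the failing check named", {
  expect_error(
    registerMethod("bad-length", function(values, params)
      list(estimate = numeric(5), valid = rep(TRUE, 5)), overwrite = TRUE),
    "length")
  expect_error(
    registerMethod("bad-shape", function(values, params) 42,
                   overwrite = TRUE),
    "TVCSeries")
  expect_error(
    registerMethod("bad-finite", function(values, params)
      list(estimate = rep(NA_real_, nrow(values)),
           valid = rep(TRUE, nrow(values))), overwrite = TRUE),
    "non-finite")
  expect_error(
    registerMethod("bad-range", function(values, params)
      list(estimate = rep(7, nrow(values)),
           valid = rep(TRUE, nrow(values))), overwrite = TRUE),
    "\\[-1, 1\\]")
  expect_error(registerMethod("JC", function(values, params) NULL),
               "already registered")
})

test_that("a constant method is isolated as a failure, not a crash", {
  registerMethod("const0", function(values, params)
    list(estimate = numeric(nrow(values)), valid = rep(TRUE, nrow(values))),
    overwrite = TRUE)
  ds <- simulateSim2(400L, seed = 2)
  ev <- evaluateCondition(ds, methods = c("JC", "SW-15", "const0"),
                          mcmc = quickMcmc(3))
  expect_true("const0" %in% names(ev$failures))
  expect_match(ev$failures[["const0"]], "constant")
  expect_setequal(ev$comparison$method, c("JC", "SW-15"))
})

test_that("an oracle regressor wins and pure noise never does", {
  for (seed in 1:5) {
    ds <- simulateSim2(600L, alpha = 0.25, seed = seed)
    truth <- truthTrack(ds)
    registerMethod("oracle", function(values, params)
      list(estimate = truth[seq_len(nrow(values))],
           valid = rep(TRUE, nrow(values))),
      overwrite = TRUE)
    noise <- withr::with_seed(1000 + seed, rnorm(600))
    registerMethod("noise", function(values, params)
      list(estimate = tanh(noise[seq_len(nrow(values))]),
           valid = rep(TRUE, nrow(values))),
      overwrite = TRUE)
    ev <- evaluateCondition(ds, methods = c("oracle", "JC", "SW-15", "noise"),
                            mcmc = quickMcmc(seed))
    expect_equal(ev$comparison$method[1], "oracle")
    expect_false(ev$comparison$method[1] == "noise")
    expect_false(ev$comparison$method[2] == "noise")
  }
})

test_that("the benchmark is deterministic under a fixed master seed", {
  cfg <- benchmarkConfig(simulations = c(1, 2),
                         sim2Grid = data.frame(alpha = 0.25, sigmaR = 0.1),
                         tLength = 400L, mcmc = quickMcmc(),
                         masterSeed = 99)
  r1 <- runBenchmark(cfg)
  r2 <- runBenchmark(cfg)
  expect_identical(r1@similarity, r2@similarity)
  lab <- names(r1@conditions)[1]
  expect_identical(r1@conditions[[lab]]$comparison,
                   r2@conditions[[lab]]$comparison)
  r3 <- runBenchmark(benchmarkConfig(simulations = c(1, 2),
                                     sim2Grid = data.frame(alpha = 0.25,
                                                           sigmaR = 0.1),
                                     tLength = 400L, mcmc = quickMcmc(),
                                     masterSeed = 100))
  expect_false(identical(r1@similarity, r3@similarity))
})

test_that("the default grid enumerates the full condition set", {
  cfg <- benchmarkConfig()
  conds <- tvcbench:::benchmarkConditions(cfg)
  # 9 fluctuating-covariance + 3 HRF + 2 state conditions
  expect_length(conds, 14L)
  labels <- vapply(conds, `[[`, "", "label")
  expect_equal(sum(grepl("^sim2", labels)), 9L)
  expect_equal(sum(grepl("^sim3", labels)), 3L)
  expect_equal(sum(grepl("^sim4", labels)), 2L)
  expect_length(cfg@methods, 7L)
})

test_that("similarity matrices from a benchmark run are well-formed", {
  cfg <- benchmarkConfig(simulations = 1L, tLength = 400L,
                         masterSeed = 5)
  rep1 <- runBenchmark(cfg)
  s <- rep1@similarity
  expect_equal(dim(s), c(7L, 7L))
  expect_equal(unname(diag(s)), rep(1, 7))
  expect_equal(unname(s), unname(t(s)))
  expect_setequal(colnames(s), defaultMethods())
})

test_that("scaleConfig shrinks sizes but preserves grids and methods", {
  cfg <- benchmarkConfig(masterSeed = 1)
  small <- scaleConfig(cfg, tSmall = 1000L, drawsSmall = 550L)
  expect_equal(small@tLength, 1000L)
  expect_equal(small@mcmc@draws, 550L)
  expect_identical(small@sim2Grid, cfg@sim2Grid)
  expect_identical(small@methods, cfg@methods)
  expect_error(scaleConfig(cfg, tSmall = 100L), "200")
  # masks recompute consistently: 1000 - 2 * 14 edge points
  ds <- simulateSim2(1000L, seed = 3)
  run <- tvcbench:::runMethods(defaultMethods(), ds)
  expect_equal(sum(commonValidMask(run$series)), 972L)
})

test_that("report bundles are written with a stable schema", {
  cfg <- benchmarkConfig(simulations = c(1, 2),
                         sim2Grid = data.frame(alpha = 0, sigmaR = 0.1),
                         tLength = 400L, mcmc = quickMcmc(),
                         masterSeed = 7)
  rep1 <- runBenchmark(cfg)
  dir <- withr::local_tempdir()
  writeReport(rep1, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  # minimal schema: required keys with the right shapes
  expect_true(all(c("version", "config", "similarity", "conditions")
                  %in% names(js)))
  expect_type(js$version, "character")
  expect_true(all(c("simulations", "tLength", "methods", "masterSeed",
                    "mcmc") %in% names(js$config)))
  expect_length(js$conditions, 1L)
  cond <- js$conditions[[1]]
  expect_true(all(c("condition", "seed", "nMask", "comparison",
                    "posteriors", "failures") %in% names(cond)))
  cmpRow <- cond$comparison[[1]]
  expect_true(all(c("method", "waic", "waicSE", "deltaWaic")
                  %in% names(cmpRow)))
  expect_type(cmpRow$waic, "double")
  tables <- list.files(file.path(dir, "tables"))
  expect_true("similarity.csv" %in% tables)
  expect_true("comparisons.csv" %in% tables)
  tab <- read.csv(file.path(dir, "tables", "comparisons.csv"))
  expect_named(tab, c("sim", "params", "method", "waic", "waic_se",
                      "delta_waic", "slope_mean", "slope_mode", "frac_gt0"))
})

test_that("dataset and series writers round-trip through plain text", {
  dir <- withr::local_tempdir()
  ds <- simulateSim4(300L, sigmaR = 0.1, seed = 8)
  p <- file.path(dir, "ds.csv")
  writeDataset(ds, p)
  df <- read.csv(p)
  expect_named(df, c("t", "x", "y", "r_true", "mu_t", "sim_id"))
  expect_equal(df$x, unname(pairValues(ds)[, 1]), tolerance = 1e-12)
  expect_equal(df$r_true, truthTrack(ds), tolerance = 1e-12)
  expect_true(file.exists(paste0(p, ".schedule.json")))
  sched <- jsonlite::read_json(paste0(p, ".schedule.json"))
  expect_equal(unlist(sched$durationSet), c(20, 30, 40, 50, 60))
  # ROI matrix reader accepts the same layout
  roi <- file.path(dir, "roi.csv")
  write.csv(data.frame(a = df$x, b = df$y), roi, row.names = FALSE)
  m <- readRoiMatrix(roi)
  expect_equal(dim(m), c(300L, 2L))
  expect_equal(colnames(m), c("a", "b"))
  # long-format TVC writer
  s <- jackknifeCorrelation(ds)
  writeTvcSeries(list(s), file.path(dir, "tvc.csv"))
  tv <- read.csv(file.path(dir, "tvc.csv"))
  expect_named(tv, c("t", "method", "estimate", "valid"))
  expect_equal(nrow(tv), 300L)
})

test_that("YAML configurations mirror the constructor arguments", {
  dir <- withr::local_tempdir()
  yml <- file.path(dir, "cfg.yaml")
  writeLines(c(
    "simulations: [2, 4]",
    "tLength: 2000",
    "masterSeed: 11",
    "methods: [JC, SD, SW-15]",
    "sim2:",
    "  alpha: [0, 0.5]",
    "  sigmaR: [0.1]",
    "sim4:",
    "  conditions: [slow]",
    "  sigmaR: 0.1",
    "mcmc:",
    "  draws: 1100",
    "  burn: 100"), yml)
  cfg <- readBenchmarkConfig(yml)
  expect_equal(cfg@simulations, c(2L, 4L))
  expect_equal(cfg@tLength, 2000L)
  expect_equal(nrow(cfg@sim2Grid), 2L)
  expect_equal(cfg@sim4Conditions, "slow")
  expect_equal(cfg@mcmc@draws, 1100L)
  expect_equal(cfg@methods, c("JC", "SD", "SW-15"))
})
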