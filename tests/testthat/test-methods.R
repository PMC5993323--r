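test_that("weighted Pearson reduces to, restricts to, and extends cor()", {
  withr::with_seed(1, {
    x <- rnorm(40); y <- rnorm(40)
  })
  expect_equal(weightedPearson(x, y, rep(1, 40)), cor(x, y),
               tolerance = 1e-12)
  # zero weights exclude points: equals cor() on the windowed subset
  w <- rep(0, 40); w[11:25] <- 1
  expect_equal(weightedPearson(x, y, w), cor(x[11:25], y[11:25]),
               tolerance = 1e-12)
  # non-uniform weights match the independent cov.wt route
  w2 <- withr::with_seed(2, runif(40))
  expect_equal(weightedPearson(x, y, w2), oracleWeightedPearson(x, y, w2),
               tolerance = 1e-12)
  # the triple (1,2,3),(1,2,3) left by w is perfectly linear
  expect_equal(weightedPearson(c(1, 2, 3, 4), c(1, 2, 3, 5), c(1, 1, 1, 0)),
               1)
  expect_error(weightedPearson(rep(1, 4), y[1:4], rep(1, 4)), "degenerate")
  expect_error(weightedPearson(x[1:4], y[1:4], c(1, 0, 0, 0)), "positive")
})

test_that("sliding window matches explicit windowed correlations", {
  v <- pairValues(simulateSim1(80L, seed = 3))
  for (L in c(9L, 15L)) {
    s <- slidingWindow(v, windowSpec(L))
    expect_equal(tvcEstimate(s)[validMask(s)],
                 oracleSlidingWindow(v, L)[validMask(s)],
                 tolerance = 1e-10)
    expect_equal(sum(validMask(s)), 80L - (L - 1L))
  }
})

test_that("sliding window handles degenerate and boundary windows", {
  v <- pairValues(simulateSim1(81L, seed = 4))
  # window covering everything leaves a single estimate = full-series cor
  s <- slidingWindow(v, windowSpec(81L))
  expect_equal(sum(validMask(s)), 1L)
  expect_equal(tvcEstimate(s)[41], cor(v[, 1], v[, 2]), tolerance = 1e-10)
  # perfectly correlated pair
  s1 <- slidingWindow(cbind(v[, 1], v[, 1]), windowSpec(15))
  expect_true(all(abs(tvcEstimate(s1)[validMask(s1)] - 1) < 1e-10))
  expect_error(slidingWindow(v, windowSpec(83L)), "longer")
  expect_error(windowSpec(14L), "odd")
})

test_that("tapered window matches per-window weighted correlations", {
  v <- pairValues(simulateSim1(60L, seed = 5))
  s <- taperedSlidingWindow(v, windowSpec(7L, 4))
  expect_equal(tvcEstimate(s)[validMask(s)],
               oracleTaperedWindow(v, 7L, 4)[validMask(s)],
               tolerance = 1e-10)
  s1 <- taperedSlidingWindow(cbind(v[, 1], v[, 1]), windowSpec(15, 100))
  expect_true(all(abs(tvcEstimate(s1)[validMask(s1)] - 1) < 1e-10))
})

test_that("taper flattens to the plain sliding window as variance grows", {
  v <- pairValues(simulateSim1(500L, seed = 6))
  sw <- slidingWindow(v, windowSpec(29))
  tsw <- taperedSlidingWindow(v, windowSpec(29, 1e8))
  m <- validMask(sw)
  expect_lt(max(abs(tvcEstimate(sw)[m] - tvcEstimate(tsw)[m])), 1e-6)
})

test_that("spatial distance matches the brute-force weight-matrix oracle", {
  v <- pairValues(simulateSim1(30L, seed = 7))
  s <- spatialDistanceTvc(v)
  expect_true(all(validMask(s)))
  expect_equal(tvcEstimate(s), oracleSpatialDistance(v, v[, 1], v[, 2]),
               tolerance = 1e-10)
  # coincident points: duplicate a row, estimates stay finite
  v2 <- v; v2[5, ] <- v2[9, ]
  expect_true(all(is.finite(tvcEstimate(spatialDistanceTvc(v2)))))
})

test_that("multivariate spatial distance shares weights across edges", {
  withr::with_seed(8, m <- matrix(rnorm(40 * 3), 40, 3,
                                  dimnames = list(NULL, c("a", "b", "c"))))
  edges <- spatialDistanceTvc(m, mode = "multivariate")
  expect_named(edges, c("a-b", "a-c", "b-c"))
  expect_equal(tvcEstimate(edges[["a-b"]]),
               oracleSpatialDistance(m, m[, 1], m[, 2]), tolerance = 1e-10)
  # bivariate mode uses only the edge's own two columns
  biv <- spatialDistanceTvc(m, mode = "bivariate")
  expect_equal(tvcEstimate(biv[["a-b"]]),
               oracleSpatialDistance(m[, 1:2], m[, 1], m[, 2]),
               tolerance = 1e-10)
})

test_that("jackknife fast path equals the naive leave-one-out", {
  for (seed in 1:3) {
    v <- pairValues(simulateSim1(sample(50:200, 1), seed = seed))
    jc <- jackknifeCorrelation(v)
    expect_true(all(validMask(jc)))
    expect_lt(max(abs(tvcEstimate(jc) - oracleJackknife(v))), 1e-10)
  }
})

test_that("jackknife of a perfectly linear pair is -1 everywhere", {
  jc <- jackknifeCorrelation(cbind(0:2, 0:2))
  expect_equal(tvcEstimate(jc), rep(-1, 3))
})

test_that("the value at t does not influence its own jackknife estimate", {
  v <- pairValues(simulateSim1(100L, seed = 9))
  jc0 <- tvcEstimate(jackknifeCorrelation(v))
  v2 <- v; v2[37, 1] <- 50; v2[37, 2] <- -20
  jc1 <- tvcEstimate(jackknifeCorrelation(v2))
  expect_equal(jc1[37], jc0[37], tolerance = 1e-8)
  expect_false(isTRUE(all.equal(jc1[-37], jc0[-37])))
})

test_that("SD and JC are permutation-invariant; windowed methods are not", {
  v <- pairValues(simulateSim1(60L, seed = 10))
  perm <- withr::with_seed(11, sample(60L))
  vp <- v[perm, ]
  expect_equal(tvcEstimate(jackknifeCorrelation(vp)),
               tvcEstimate(jackknifeCorrelation(v))[perm], tolerance = 1e-10)
  expect_equal(tvcEstimate(spatialDistanceTvc(vp)),
               tvcEstimate(spatialDistanceTvc(v))[perm], tolerance = 1e-10)
  sw <- tvcEstimate(slidingWindow(v, windowSpec(9)))
  swp <- tvcEstimate(slidingWindow(vp, windowSpec(9)))
  expect_false(isTRUE(all.equal(swp, sw[perm])))
  mt <- tvcEstimate(mtd(v))
  mtp <- tvcEstimate(mtd(vp))
  expect_false(isTRUE(all.equal(mtp, mt[perm])))
})

test_that("jackknife variance compression grows with series length", {
  short <- constantCovPair(400L, 0.5, seed = 12)
  long <- constantCovPair(4000L, 0.5, seed = 12)
  expect_lt(sd(tvcEstimate(jackknifeCorrelation(long))),
            sd(tvcEstimate(jackknifeCorrelation(short))))
})

test_that("leave-n-out generalizes the jackknife", {
  v <- pairValues(simulateSim1(120L, seed = 13))
  expect_equal(tvcEstimate(leaveNOutCorrelation(v, 1L)),
               tvcEstimate(jackknifeCorrelation(v)), tolerance = 1e-12)
  for (n in c(2L, 7L, 50L))
    expect_equal(tvcEstimate(leaveNOutCorrelation(v, n)),
                 oracleLeaveNOut(v, n), tolerance = 1e-9)
  # n = T - 2 leaves exactly two points wherever the excluded block is not
  # truncated by the series edges: their correlation is +/-1, negated
  n <- nrow(v) - 2L
  est <- tvcEstimate(leaveNOutCorrelation(v, n))
  centre <- ((n - 1L) %/% 2L + 1L):(nrow(v) - n %/% 2L)
  expect_true(length(centre) >= 1L &&
                all(abs(abs(est[centre]) - 1) < 1e-9))
  expect_error(leaveNOutCorrelation(v, nrow(v) - 1L), "n")
})

test_that("leave-n-out mirrors window-length-n on stepped-covariance data", {
  ds <- steppedCovPair(10000L, seed = 14)
  v <- pairValues(ds)
  for (n in c(101L, 1001L, 4999L)) {
    lno <- leaveNOutCorrelation(v, n)
    sw <- slidingWindow(v, windowSpec(n))
    m <- validMask(sw) & validMask(lno)
    rho <- cor(tvcEstimate(lno)[m], tvcEstimate(sw)[m], method = "spearman")
    expect_gt(rho, 0.95)
  }
})

test_that("MTD matches its definition and flags degenerate input", {
  v <- pairValues(simulateSim1(100L, seed = 15))
  s <- mtd(v, 7L)
  expect_equal(tvcEstimate(s)[validMask(s)],
               oracleMtd(v, 7L)[validMask(s)], tolerance = 1e-10)
  expect_equal(sum(validMask(s)), 100L - 7L)
  # identical derivative series: raw coupling is z^2 / var(z), mean ~ 1
  z <- withr::with_seed(16, cumsum(rnorm(2000)))
  raw <- mtd(cbind(z, z), 1L)
  expect_true(all(tvcEstimate(raw)[validMask(raw)] >= 0))
  expect_equal(mean(tvcEstimate(raw)[validMask(raw)]), 1, tolerance = 0.01)
  # smoothing window 1 is the identity on the raw coupling
  s1 <- mtd(v, 1L)
  expect_equal(sum(validMask(s1)), 99L)
  expect_error(mtd(cbind(1:50, rnorm(50)), 7L), "zero variance")
  expect_error(mtd(v, 4L), "odd")
})

test_that("Fisher transform is atanh with clamping, correlation-scale only", {
  s <- newSeries(c(0, 0.5, -0.3, 1), rep(TRUE, 4))
  z <- tvcEstimate(fisherTransform(s))
  expect_equal(z[1], 0)
  expect_equal(z[2], atanh(0.5), tolerance = 1e-10)
  expect_equal(z[2], 0.5 * log(3), tolerance = 1e-10)
  expect_true(is.finite(z[4]))  # exact 1 clamped before atanh
  # strictly monotone over the valid range
  g <- newSeries(seq(-0.9, 0.9, by = 0.1), rep(TRUE, 19))
  expect_true(all(diff(tvcEstimate(fisherTransform(g))) > 0))
  expect_error(fisherTransform(mtd(pairValues(simulateSim1(50L, seed = 1)))),
               "product-scale")
})

test_that("standardization is idempotent with population sd", {
  withr::with_seed(17, s <- newSeries(rnorm(200, 5, 3), rep(TRUE, 200)))
  z1 <- standardizeSeries(s)
  expect_equal(mean(tvcEstimate(z1)), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(tvcEstimate(z1)^2)), 1, tolerance = 1e-12)
  z2 <- standardizeSeries(z1)
  expect_equal(tvcEstimate(z2), tvcEstimate(z1), tolerance = 1e-12)
  expect_error(standardizeSeries(newSeries(rep(2, 10), rep(TRUE, 10))),
               "constant")
  # masked standardization uses only masked points for the moments
  mask <- c(rep(TRUE, 100), rep(FALSE, 100))
  zm <- standardizeSeries(s, mask = mask)
  expect_equal(mean(tvcEstimate(zm)[mask]), 0, tolerance = 1e-12)
})

test_that("common mask intersects validity and catches errors", {
  a <- newSeries(rnorm(10), c(FALSE, rep(TRUE, 8), FALSE))
  b <- newSeries(rnorm(10), c(rep(TRUE, 9), FALSE))
  expect_equal(sum(commonValidMask(list(a, b))), 8L)
  expect_error(commonValidMask(list(a, newSeries(rnorm(5), rep(TRUE, 5)))),
               "length")
  expect_error(commonValidMask(list(
    newSeries(rnorm(4), rep(FALSE, 4)),
    newSeries(rnorm(4), rep(TRUE, 4)))), "empty")
})
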