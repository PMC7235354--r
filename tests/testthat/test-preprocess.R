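test_that("initial-volume discard truncates and validates", {
  ts <- roiTimeSeries(matrix(rnorm(250 * 4), 250, 4))
  expect_equal(nVolumes(discardInitial(ts)), 240)
  expect_identical(seriesData(discardInitial(ts, 0)), seriesData(ts))
  ts5 <- roiTimeSeries(matrix(rnorm(5 * 4), 5, 4))
  expect_error(discardInitial(ts5, 5), "discard")
})

test_that("Friston-24 expansion matches the explicit construction", {
  # all-zero and constant traces
  z <- matrix(0, 10, 6)
  expect_equal(friston24(z), oracleFriston24(z), ignore_attr = TRUE)
  expect_true(all(friston24(z) == 0))
  cst <- matrix(rep(c(1, -2, 0.5, 0.1, -0.1, 0.2), each = 10), 10, 6)
  f <- friston24(cst)
  expect_equal(unname(f[2, 1:6]), cst[1, ])          # raw params
  expect_equal(unname(f[2, 13:18]), cst[1, ]^2)      # squares
  expect_equal(unname(f[1, 7:12]), rep(0, 6))        # lag zero-padded
  expect_equal(unname(f[3, 7:12]), cst[2, ])
  # random trace vs brute-force column-by-column oracle
  set.seed(42)
  p <- matrix(rnorm(60), 10, 6)
  expect_equal(unname(friston24(p)), oracleFriston24(p))
  expect_error(friston24(p[, 1:5]), "6 motion")
})

test_that("framewise displacement follows the translation+arc-length rule", {
  z <- matrix(0, 10, 6)
  expect_equal(computeFd(z), rep(0, 10))
  # single 0.1 mm x-translation step between frames 3 and 4
  p <- z; p[4:10, 1] <- 0.1
  fd <- computeFd(p)
  expect_equal(fd[4], 0.1)
  expect_equal(fd[-4], rep(0, 9))
  # single 0.002 rad rotation step at 50 mm radius -> 0.1 mm arc length
  q <- z; q[6:10, 5] <- 0.002
  expect_equal(computeFd(q, headRadius = 50)[6], 0.1)
  expect_error(computeFd(matrix(c(1, NA), 2, 6)), "finite")
})

test_that("FD depends only on successive differences (position invariance)", {
  set.seed(7)
  p <- matrix(rnorm(60, sd = 0.05), 10, 6)
  shift <- matrix(rep(rnorm(6, sd = 5), each = 10), 10, 6)
  expect_equal(computeFd(p + shift), computeFd(p))
})

test_that("motion QC excludes strictly above the mean-FD threshold", {
  mkTrace <- function(step) {
    # 5 frames, constant x-step: mean FD = 4 * step / 5
    p <- matrix(0, 5, 6)
    p[, 1] <- step * (0:4)
    motionTrace(p)
  }
  # steps 0.25 * (0:4) are exact binary fractions: mean FD == 1/5 exactly
  tr <- list(low = mkTrace(0.2375), edge = mkTrace(0.25),
             high = mkTrace(0.2625))
  expect_identical(meanFd(tr$edge), 1 / 5)
  qc <- qcExclude(tr, threshold = 0.2)
  expect_equal(qc$kept, c(TRUE, TRUE, FALSE))  # exactly 0.2 is kept
  zeros <- list(a = motionTrace(matrix(0, 5, 6)),
                b = motionTrace(matrix(0, 5, 6)))
  expect_true(all(qcExclude(zeros)$kept))
})

test_that("nuisance regression produces orthogonal OLS residuals", {
  set.seed(1)
  Y <- matrix(rnorm(50 * 3), 50, 3)
  ts <- roiTimeSeries(Y)
  # no regressors: demeaning
  out0 <- nuisanceRegress(ts)
  expect_equal(seriesData(out0), scale(Y, scale = FALSE), ignore_attr = TRUE)
  # a ROI that IS a regressor has all-zero residuals
  X <- cbind(Y[, 1], rnorm(50))
  out1 <- nuisanceRegress(ts, X)
  expect_lt(max(abs(seriesData(out1)[, 1])), 1e-10)
  # elementwise match with the normal-equations oracle
  expect_lt(max(abs(seriesData(out1) - oracleOlsResiduals(Y, X))), 1e-10)
  # residuals orthogonal to every regressor column
  expect_lt(max(abs(crossprod(X, seriesData(out1)))), 1e-8)
  # invariance to invertible reparameterisation of the regressor set
  A <- matrix(c(2, 1, 0.5, -1), 2, 2)
  out2 <- nuisanceRegress(ts, X %*% A)
  expect_equal(seriesData(out2), seriesData(out1), tolerance = 1e-10)
  # rank deficiency is named
  expect_error(nuisanceRegress(ts, cbind(a = X[, 1], b = 2 * X[, 1])),
               "collinear")
})

test_that("boxcar band-pass keeps in-band sinusoids and removes the rest", {
  Tn <- 240; tr <- 2
  t <- seq_len(Tn) * tr
  inband <- sin(2 * pi * 0.05 * t)       # exact DFT bin at these settings
  outband <- sin(2 * pi * 0.2 * t + 0.3)
  const <- rep(3, Tn)
  ts <- roiTimeSeries(cbind(inband, outband, const) + 0, tr = tr)
  f <- seriesData(bandpassFilter(ts))
  expect_equal(max(abs(f[, 1])) / max(abs(inband)), 1, tolerance = 0.01)
  expect_lt(max(abs(f[, 2])), 0.01 * max(abs(outband)))
  expect_lt(max(abs(f[, 3])), 1e-10)
  expect_lt(max(abs(colMeans(f))), 1e-10)
  expect_error(bandpassFilter(ts, 0.01, 0.3), "Nyquist")
})

test_that("filtering twice equals filtering once (idempotence)", {
  set.seed(3)
  ts <- roiTimeSeries(matrix(rnorm(240 * 3), 240, 3), tr = 2)
  once <- bandpassFilter(ts)
  twice <- bandpassFilter(once)
  expect_equal(seriesData(twice), seriesData(once), tolerance = 1e-10)
})

test_that("preprocessSubject chains discard, regression and filtering", {
  set.seed(5)
  ts <- roiTimeSeries(matrix(rnorm(250 * 5), 250, 5), tr = 2)
  mot <- motionTrace(apply(matrix(rnorm(250 * 6, sd = 0.01), 250, 6), 2, cumsum))
  clean <- preprocessSubject(ts, mot)
  expect_equal(nVolumes(clean), 240)
  expect_lt(max(abs(colMeans(seriesData(clean)))), 1e-10)
  # GSR changes the result
  gsr <- preprocessSubject(ts, mot, gsr = TRUE)
  expect_false(isTRUE(all.equal(seriesData(gsr), seriesData(clean))))
})
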