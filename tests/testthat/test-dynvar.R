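test_that("window segmentation counts and discards follow the floor rule", {
  expect_equal(nrow(segmentWindows(240, 30, 1)), 8)
  w <- segmentWindows(240, 21, 1)
  expect_equal(nrow(w), 11)                 # last 9 volumes discarded
  expect_equal(unname(w[11, "end"]), 231L)
  expect_equal(nrow(segmentWindows(240, 30, 5)), 7)
  # windows are contiguous, equal length, non-overlapping
  expect_true(all(diff(w[, "start"]) == 21))
  expect_true(all(w[, "end"] - w[, "start"] == 20))
  expect_error(segmentWindows(240, 30, 30), "offset")
  expect_error(segmentWindows(10, 21, 1), "no full window")
})

test_that("windowed FC is Pearson with affine invariance and NA flagging", {
  set.seed(2)
  base <- rnorm(20)
  mat <- cbind(a = base, b = 2 * base + 3, c = -base, d = rnorm(20))
  fc <- windowFc(mat, 1, 20)
  expect_equal(fc[1, 2], 1)
  expect_equal(fc[1, 3], -1)
  expect_equal(diag(fc), rep(1, 4), ignore_attr = TRUE)
  expect_equal(fc, t(fc))
  # hand-computed small block
  m2 <- matrix(c(1, 2, 4, 3, 7, 2, 1, 5, 3, 6, 9, 4, 2, 8, 1), 5, 3)
  expect_equal(windowFc(m2, 1, 5), oracleWindowFc(m2, 1, 5),
               tolerance = 1e-12, ignore_attr = TRUE)
  # constant ROI flags its row/column
  m3 <- cbind(rnorm(10), rep(1, 10), rnorm(10))
  fc3 <- windowFc(m3, 1, 10)
  expect_true(all(is.na(fc3[2, -2])) && all(is.na(fc3[-2, 2])))
  expect_false(anyNA(fc3[-2, -2]))
  expect_error(windowFc(m3, 9, 3), "outside")
})

test_that("identical windows give V = 0 and anticorrelated patterns V = 2", {
  # stack of identical FC matrices: periodic series, period = window length
  set.seed(4)
  block <- matrix(rnorm(10 * 5), 10, 5)
  ts <- roiTimeSeries(rbind(block, block, block), tr = 2)
  st <- windowFcStack(ts, l = 10, s = 1)
  expect_equal(dim(st@fc)[3], 3)
  vr <- regionalVariability(st)
  expect_equal(unname(vr), rep(0, 5), tolerance = 1e-12)
  expect_equal(intraNetworkVariability(st, 1:5), 0, tolerance = 1e-12)
  expect_equal(interNetworkVariability(st, 1:2, 3:5), 0, tolerance = 1e-12)

  # two windows with exactly anticorrelated pattern vectors
  fcA <- diag(4); fcA[upper.tri(fcA)] <- c(0.5, -0.2, 0.1, 0.4, -0.3, 0.2)
  fcA <- fcA + t(fcA); diag(fcA) <- 1
  fcB <- -fcA; diag(fcB) <- 1
  st2 <- new("WindowFcStack", fc = array(c(fcA, fcB), c(4, 4, 2)),
             starts = c(1L, 5L), windowLength = 4L)
  expect_equal(unname(regionalVariability(st2)), rep(2, 4), tolerance = 1e-12)
  expect_equal(intraNetworkVariability(st2, 1:4), 2, tolerance = 1e-12)
})

test_that("variability statistics match the brute-force oracle", {
  set.seed(9)
  for (rep in 1:20) {
    R <- sample(4:8, 1); num <- sample(3:5, 1); len <- sample(5:9, 1)
    st <- makeRandomStack(R, num, len, seed = 100 + rep)
    fcs <- lapply(seq_len(num), function(i) st@fc[, , i])
    for (k in sample(R, 2))
      expect_equal(regionalVariability(st, k), oracleRegional(fcs, k),
                   tolerance = 1e-12)
    mem <- sample(R, 3); rest <- setdiff(1:R, mem)
    expect_equal(intraNetworkVariability(st, mem), oracleIntra(fcs, mem),
                 tolerance = 1e-12)
    if (length(rest) >= 1)
      expect_equal(interNetworkVariability(st, mem, rest),
                   oracleInter(fcs, mem, rest), tolerance = 1e-12)
  }
})

test_that("inter-network variability is symmetric and rejects overlap", {
  st <- makeRandomStack(8, 4, 7, seed = 5)
  expect_equal(interNetworkVariability(st, 1:3, 4:8),
               interNetworkVariability(st, 4:8, 1:3), tolerance = 1e-14)
  expect_error(interNetworkVariability(st, 1:3, 3:5), "overlap")
})

test_that("a 2-ROI network has no intra-network value", {
  st <- makeRandomStack(6, 4, 7, seed = 6)
  expect_true(is.na(intraNetworkVariability(st, 1:2)))
  expect_true(is.na(intraNetworkVariability(st, 3)))
})

test_that("multi-scale averaging uses all (l, s) segmentations", {
  set.seed(10)
  ts <- roiTimeSeries(matrix(rnorm(240 * 5), 240, 5), tr = 2)
  p <- syntheticParcellation(5, 2)
  prof <- multiscaleVariability(ts, p)       # default scheme, l = 21..30
  expect_equal(prof@nSegmentationsUsed, 245) # sum over l of (l - 1)
  expect_length(regionalVariability(prof), 5)
  expect_length(intraNetworkVariability(prof), 2)
  expect_length(interNetworkVariability(prof), 1)

  expect_error(multiscaleVariability(roiTimeSeries(matrix(rnorm(10 * 3), 10, 3)),
                                     syntheticParcellation(3, 1),
                                     windowScheme(21:30)),
               "no valid segmentation")
})

test_that("single-segmentation scheme equals the raw per-segmentation value", {
  set.seed(12)
  ts <- roiTimeSeries(matrix(rnorm(80 * 6), 80, 6), tr = 2)
  p <- syntheticParcellation(6, 2)
  # l = 40, offsets s = 1..39, but only s = 1 yields 2 full windows
  prof <- multiscaleVariability(ts, p, windowScheme(40, minWindows = 2))
  expect_equal(prof@nSegmentationsUsed, 1L)
  st <- windowFcStack(ts, 40, 1)
  expect_equal(regionalVariability(prof), regionalVariability(st),
               tolerance = 1e-12)
})

test_that("full multi-scale profile equals the naive reference pipeline", {
  set.seed(13)
  for (rep in 1:3) {
    R <- sample(4:6, 1)
    mat <- matrix(rnorm(60 * R), 60, R)
    p <- syntheticParcellation(R, 2)
    prof <- multiscaleVariability(roiTimeSeries(mat), p,
                                  windowScheme(10:12))
    ref <- oracleMultiscale(mat, p, 10:12)
    expect_equal(unname(regionalVariability(prof)), ref$regional,
                 tolerance = 1e-10)
    expect_equal(unname(intraNetworkVariability(prof)), ref$intra,
                 tolerance = 1e-10)
    expect_equal(unname(interNetworkVariability(prof)), ref$inter,
                 tolerance = 1e-10)
  }
})

test_that("variability is invariant to affine rescaling of any ROI", {
  set.seed(14)
  mat <- matrix(rnorm(100 * 5), 100, 5)
  p <- syntheticParcellation(5, 2)
  sch <- windowScheme(20:22)
  a <- multiscaleVariability(roiTimeSeries(mat), p, sch)
  mat2 <- mat
  mat2[, 2] <- 3.7 * mat[, 2] + 11
  mat2[, 5] <- 0.01 * mat[, 5] - 2
  b <- multiscaleVariability(roiTimeSeries(mat2), p, sch)
  expect_equal(regionalVariability(b), regionalVariability(a),
               tolerance = 1e-10)
  expect_equal(interNetworkVariability(b), interNetworkVariability(a),
               tolerance = 1e-10)
})

test_that("defined variability values stay within [0, 2] under stress", {
  set.seed(15)
  for (rep in 1:10) {
    R <- sample(3:10, 1)
    Tn <- sample(50:120, 1)
    mat <- matrix(rnorm(Tn * R), Tn, R)
    # inject pathological columns: constants, spikes, tiny variance
    if (rep %% 2 == 0) mat[, 1] <- 1
    if (rep %% 3 == 0) mat[5, ] <- 1e6
    p <- syntheticParcellation(R, min(3, R))
    prof <- suppressWarnings(
      multiscaleVariability(roiTimeSeries(mat), p, windowScheme(10:14)))
    v <- c(regionalVariability(prof), intraNetworkVariability(prof),
           interNetworkVariability(prof))
    v <- v[!is.na(v)]
    expect_true(all(v >= -1e-10 & v <= 2 + 1e-10))
  }
})

test_that("flattenProfile emits lexicographic inter-network columns", {
  st_ts <- roiTimeSeries(matrix(rnorm(60 * 6), 60, 6))
  p <- newParcellation(paste0("r", 1:6),
                       rep(c("zeta", "alpha", "mid"), each = 2))
  prof <- multiscaleVariability(st_ts, p, windowScheme(15))
  row <- flattenProfile(prof)
  internames <- grep("^inter_", names(row), value = TRUE)
  expect_equal(internames, sort(internames))
  expect_true("inter_alpha__zeta" %in% internames)   # pair sorted within name
  expect_equal(row$n_segmentations_used, prof@nSegmentationsUsed)
})

test_that("Fisher-z option changes values but keeps them defined", {
  set.seed(16)
  ts <- roiTimeSeries(matrix(rnorm(100 * 5), 100, 5))
  p <- syntheticParcellation(5, 2)
  raw <- multiscaleVariability(ts, p, windowScheme(20:22))
  fz <- multiscaleVariability(ts, p, windowScheme(20:22), fisherZ = TRUE)
  expect_false(isTRUE(all.equal(regionalVariability(raw),
                                regionalVariability(fz))))
  expect_false(anyNA(regionalVariability(fz)))
})
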