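#' Discard initial volumes
#'
#' Removes the first \code{nDiscard} volumes of a series, the standard
#' guard against pre-steady-state magnetisation (default 10, so a 250-volume
#' acquisition yields 240 analysed volumes).
#'
#' @param ts a \linkS4class{RoiTimeSeries}
#' @param nDiscard number of initial volumes to drop (default 10)
#' @return the truncated \linkS4class{RoiTimeSeries}
#' @export
discardInitial <- function(ts, nDiscard = 10) {
  stopifnot(is(ts, "RoiTimeSeries"))
  Tn <- nrow(ts@data)
  if (nDiscard < 0) stop("nDiscard must be non-negative")
  if (nDiscard >= Tn)
    stop("cannot discard ", nDiscard, " volumes from a ", Tn,
         "-volume series")
  if (nDiscard == 0) return(ts)
  roiTimeSeries(ts@data[-seq_len(nDiscard), , drop = FALSE],
                tr = ts@tr, subjectId = ts@subjectId)
}

#' Build a MotionTrace from realignment parameters
#'
#' Computes framewise displacement (FD) in the Power form: for frame t >= 2,
#' FD(t) = sum |delta translation_i| + r * sum |delta rotation_j|, with the
#' rotation differences (radians) converted to arc length on a sphere of
#' radius r mm; FD(1) = 0.
#'
#' @param params numeric T x 6 matrix (tx, ty, tz mm; rx, ry, rz radians)
#' @param headRadius sphere radius in mm (default 50)
#' @return a \linkS4class{MotionTrace}
#' @export
motionTrace <- function(params, headRadius = 50) {
  params <- as.matrix(params)
  storage.mode(params) <- "double"
  if (ncol(params) != 6)
    stop("motion parameters must have 6 columns, got ", ncol(params))
  if (any(!is.finite(params)))
    stop("motion parameters contain non-finite values")
  if (headRadius <= 0) stop("headRadius must be positive")
  fd <- computeFd(params, headRadius)
  new("MotionTrace", params = params, fd = fd, meanFd = mean(fd),
      headRadius = headRadius)
}

#' Framewise displacement of a motion-parameter matrix
#'
#' @param params numeric T x 6 matrix (translations mm, rotations radians)
#' @param headRadius sphere radius in mm converting rotation to arc length
#' @return numeric vector of per-frame FD (mm), first element 0
#' @export
computeFd <- function(params, headRadius = 50) {
  params <- as.matrix(params)
  if (ncol(params) != 6) stop("expected 6 motion parameters")
  if (any(!is.finite(params))) stop("non-finite motion parameters")
  if (headRadius <= 0) stop("headRadius must be positive")
  d <- abs(diff(params))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    headRadius * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Friston-24 head-motion expansion
#'
#' Expands the 6 realignment parameters p(t) into the 24-regressor set
#' [p(t), p(t-1), p(t)^2, p(t-1)^2]. Lagged columns are zero-padded at the
#' first frame.
#'
#' @param motion a \linkS4class{MotionTrace} or a T x 6 numeric matrix
#' @return numeric T x 24 matrix, columns named p1..p6, p1_lag.., p1_sq..,
#'   p1_lag_sq..
#' @export
friston24 <- function(motion) {
  p <- if (is(motion, "MotionTrace")) motion@params else as.matrix(motion)
  if (ncol(p) != 6) stop("expected 6 motion parameters, got ", ncol(p))
  if (nrow(p) < 2) stop("need at least 2 frames")
  lag <- rbind(0, p[-nrow(p), , drop = FALSE])
  out <- cbind(p, lag, p^2, lag^2)
  colnames(out) <- c(paste0("p", 1:6), paste0("p", 1:6, "_lag"),
                     paste0("p", 1:6, "_sq"), paste0("p", 1:6, "_lag_sq"))
  out
}

#' Motion-based subject exclusion
#'
#' Splits a cohort of motion traces into kept and excluded subjects by the
#' mean-FD rule: a subject is excluded iff mean FD is strictly greater than
#' the threshold (default 0.2 mm).
#'
#' @param motions named list of \linkS4class{MotionTrace} objects (names =
#'   subject ids)
#' @param threshold exclusion threshold in mm (default 0.2)
#' @return a data.frame with columns subject_id, mean_fd, kept
#' @export
qcExclude <- function(motions, threshold = 0.2) {
  stopifnot(threshold > 0)
  if (is.null(names(motions)))
    names(motions) <- paste0("sub", seq_along(motions))
  mfd <- vapply(motions, meanFd, numeric(1))
  data.frame(subject_id = names(motions), mean_fd = unname(mfd),
             kept = unname(mfd <= threshold), row.names = NULL)
}

#' Nuisance regression of ROI signals
#'
#' Replaces each ROI signal by the residual of an ordinary least-squares fit
#' on the given regressors plus an intercept. Residuals are orthogonal to
#' every regressor column; with no regressors the result is the demeaned
#' series. Typical regressor sets are the Friston-24 motion expansion and
#' white-matter / CSF signals; pass the ROI-mean signal as an extra column
#' to perform global signal regression.
#'
#' @param ts a \linkS4class{RoiTimeSeries}
#' @param regressors numeric T x Q matrix (Q may be 0); an intercept is
#'   always appended internally
#' @return the residual \linkS4class{RoiTimeSeries}
#' @export
nuisanceRegress <- function(ts, regressors = NULL) {
  stopifnot(is(ts, "RoiTimeSeries"))
  Tn <- nrow(ts@data)
  if (is.null(regressors)) regressors <- matrix(0, Tn, 0)
  regressors <- as.matrix(regressors)
  if (nrow(regressors) != Tn)
    stop("regressors have ", nrow(regressors), " rows but the series has ",
         Tn, " volumes")
  X <- cbind(`(intercept)` = 1, regressors)
  if (is.null(colnames(X)))
    colnames(X) <- c("(intercept)", paste0("reg", seq_len(ncol(X) - 1)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient nuisance design; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  res <- ts@data - X %*% qr.coef(qrX, ts@data)
  roiTimeSeries(res, tr = ts@tr, subjectId = ts@subjectId)
}

#' Ideal (boxcar) frequency-domain band-pass filter
#'
#' Zeroes every discrete Fourier coefficient whose frequency lies outside
#' [low, high] Hz -- including the zero-frequency (mean) term -- and returns
#' the inverse transform. Each output column therefore has mean ~0. The
#' passband test is inclusive at both edges. The default band, 0.01-0.10 Hz,
#' is the conventional resting-state BOLD band.
#'
#' @param ts a \linkS4class{RoiTimeSeries}
#' @param low lower band edge in Hz (default 0.01)
#' @param high upper band edge in Hz (default 0.10)
#' @return the filtered \linkS4class{RoiTimeSeries}
#' @export
bandpassFilter <- function(ts, low = 0.01, high = 0.10) {
  stopifnot(is(ts, "RoiTimeSeries"))
  nyquist <- 1 / (2 * ts@tr)
  if (low < 0 || low >= high)
    stop("need 0 <= low < high")
  if (high > nyquist + 1e-12)
    stop("high edge ", high, " Hz exceeds the Nyquist frequency ",
         nyquist, " Hz for TR = ", ts@tr, " s")
  Tn <- nrow(ts@data)
  freq <- seq_len(Tn) - 1
  freq <- pmin(freq, Tn - freq) / (Tn * ts@tr)  # two-sided bin frequencies
  keep <- freq >= low & freq <= high
  co <- stats::mvfft(ts@data)
  co[!keep, ] <- 0
  out <- Re(stats::mvfft(co, inverse = TRUE)) / Tn
  roiTimeSeries(out, tr = ts@tr, subjectId = ts@subjectId)
}

#' Standard per-subject preprocessing chain
#'
#' Applies, in order: initial-volume discard, nuisance regression
#' (Friston-24 motion expansion, any extra confound columns, optionally the
#' global ROI-mean signal), and band-pass filtering. The step order is
#' fixed; motion regressors are built from the same frames retained after
#' the discard.
#'
#' @param ts a \linkS4class{RoiTimeSeries} (raw, pre-discard)
#' @param motion a \linkS4class{MotionTrace} aligned with `ts` frames
#' @param nDiscard initial volumes to drop (default 10)
#' @param low,high band edges in Hz (defaults 0.01, 0.10)
#' @param gsr add global signal regression? (default FALSE)
#' @param extraRegressors optional T x Q matrix of extra confounds (aligned
#'   with the raw series; rows are discarded along with the volumes)
#' @return the cleaned \linkS4class{RoiTimeSeries}
#' @export
preprocessSubject <- function(ts, motion = NULL, nDiscard = 10,
                              low = 0.01, high = 0.10, gsr = FALSE,
                              extraRegressors = NULL) {
  stopifnot(is(ts, "RoiTimeSeries"))
  keep <- (nDiscard + 1):nrow(ts@data)
  out <- discardInitial(ts, nDiscard)
  reg <- NULL
  if (!is.null(motion)) {
    p <- if (is(motion, "MotionTrace")) motion@params else as.matrix(motion)
    if (nrow(p) == nrow(ts@data)) p <- p[keep, , drop = FALSE]
    if (nrow(p) != nrow(out@data))
      stop("motion trace length matches neither the raw nor the truncated series")
    reg <- friston24(p)
  }
  if (!is.null(extraRegressors)) {
    e <- as.matrix(extraRegressors)
    if (nrow(e) == nrow(ts@data)) e <- e[keep, , drop = FALSE]
    reg <- cbind(reg, e)
  }
  if (gsr) {
    g <- rowMeans(out@data)
    reg <- cbind(reg, global = g)
  }
  out <- nuisanceRegress(out, reg)
  bandpassFilter(out, low = low, high = high)
}
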