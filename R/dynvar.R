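#' Multi-scale window scheme constructor
#'
#' @param lengths window lengths in volumes (default 21:30, i.e. 42-60 s at
#'   TR = 2 s)
#' @param minWindows minimum full windows per segmentation (default 2)
#' @return a \linkS4class{WindowScheme}
#' @export
windowScheme <- function(lengths = 21:30, minWindows = 2) {
  new("WindowScheme", lengths = as.integer(lengths),
      minWindows = as.integer(minWindows))
}

setMethod("show", "WindowScheme", function(object) {
  cat("WindowScheme: lengths", paste(range(object@lengths), collapse = "-"),
      "volumes, all offsets s = 1..l-1, minWindows =",
      object@minWindows, "\n")
  cat("  segmentations for T >= 2*max(l):",
      sum(object@lengths - 1L), "\n")
})

#' Non-overlapping window segmentation
#'
#' Starting from volume \code{s}, cuts the series into consecutive windows
#' of \code{l} volumes; the trailing partial window (and the s - 1 leading
#' volumes) are discarded. The number of windows is
#' \code{floor((T - s + 1) / l)}.
#'
#' @param T number of volumes in the series
#' @param l window length in volumes (>= 2)
#' @param s start offset, 1 <= s <= l - 1 (s = 1 starts at the first volume)
#' @return integer matrix with columns \code{start}, \code{end} (1-based,
#'   inclusive), one row per window
#' @export
segmentWindows <- function(T, l, s = 1) {
  if (l < 2) stop("window length must be >= 2")
  if (s < 1 || s > l - 1)
    stop("start offset s must satisfy 1 <= s <= l - 1")
  num <- (T - s + 1) %/% l
  if (num < 1)
    stop("no full window of length ", l, " fits in ", T,
         " volumes at offset ", s)
  starts <- s + l * (seq_len(num) - 1L)
  cbind(start = as.integer(starts), end = as.integer(starts + l - 1L))
}

#' Windowed Pearson FC matrix
#'
#' The R x R matrix of pairwise Pearson correlations of the ROI signals
#' restricted to one window. The diagonal is 1; if a ROI is constant within
#' the window its row and column are set to NA (correlation undefined).
#'
#' @param ts a \linkS4class{RoiTimeSeries} or a numeric T x R matrix
#' @param start first volume of the window (1-based)
#' @param length window length in volumes (>= 3)
#' @return numeric R x R correlation matrix
#' @export
windowFc <- function(ts, start, length) {
  m <- if (is(ts, "RoiTimeSeries")) ts@data else as.matrix(ts)
  if (length < 3) stop("window length must be >= 3 for a correlation")
  if (start < 1 || start + length - 1 > nrow(m))
    stop("window [", start, ", ", start + length - 1,
         "] is outside the series")
  w <- m[start:(start + length - 1), , drop = FALSE]
  sds <- apply(w, 2, stats::sd)
  fc <- suppressWarnings(stats::cor(w))
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    fc[bad, ] <- NA_real_
    fc[, bad] <- NA_real_
  }
  diag(fc) <- 1
  fc
}

#' Windowed FC stack for one segmentation
#'
#' @param ts a \linkS4class{RoiTimeSeries}
#' @param l window length in volumes
#' @param s start offset (1..l-1)
#' @param fisherZ apply the Fisher r-to-z transform to every off-diagonal
#'   FC value before the across-window comparison (default FALSE: the
#'   variability statistics operate on raw correlations)
#' @return a \linkS4class{WindowFcStack}
#' @export
windowFcStack <- function(ts, l, s = 1, fisherZ = FALSE) {
  stopifnot(is(ts, "RoiTimeSeries"))
  win <- segmentWindows(nrow(ts@data), l, s)
  R <- ncol(ts@data)
  fc <- array(NA_real_, c(R, R, nrow(win)))
  for (i in seq_len(nrow(win)))
    fc[, , i] <- windowFc(ts@data, win[i, "start"], l)
  if (fisherZ) {
    z <- atanh(pmin(pmax(fc, -1 + 1e-7), 1 - 1e-7))
    for (i in seq_len(nrow(win))) diag(z[, , i]) <- atanh(1 - 1e-7)
    fc <- z
  }
  dimnames(fc) <- list(colnames(ts@data), colnames(ts@data), NULL)
  new("WindowFcStack", fc = fc, starts = win[, "start"],
      windowLength = as.integer(l))
}

setMethod("show", "WindowFcStack", function(object) {
  cat("WindowFcStack:", dim(object@fc)[3], "windows of",
      object@windowLength, "volumes,", dim(object@fc)[1], "ROIs\n")
})

# Mean pairwise Pearson correlation across the rows of X (windows x pattern
# entries). Pairs whose correlation is undefined (a constant or all-NA
# pattern vector) are skipped; if more than half of the pairs are skipped the
# whole value is NA (segmentation unusable for this statistic).
meanPairCorr <- function(X) {
  num <- nrow(X)
  C <- suppressWarnings(stats::cor(t(X), use = "pairwise.complete.obs"))
  up <- C[upper.tri(C)]
  skipped <- sum(!is.finite(up))
  val <- if (skipped > length(up) / 2) NA_real_ else
    mean(up[is.finite(up)])
  list(value = val, skipped = skipped, nPairs = length(up))
}

#' @describeIn VariabilityProfile-class For a \linkS4class{WindowFcStack}:
#'   the per-ROI temporal variability V_k = 1 minus the mean, over all
#'   unordered window pairs, of the Pearson correlation between the ROI's
#'   whole-brain FC pattern vectors (row k of the windowed FC matrix with
#'   the self-correlation entry removed). Returns a named numeric vector.
#' @param k optional single ROI index; default all ROIs
#' @export
setMethod("regionalVariability", "WindowFcStack", function(x, k = NULL) {
  fc <- x@fc
  R <- dim(fc)[1]
  num <- dim(fc)[3]
  if (num < 2) stop("need at least 2 windows")
  ks <- if (is.null(k)) seq_len(R) else as.integer(k)
  if (!anyNA(fc)) {
    # moment-based fast path, vectorised over ROIs for each window pair
    rsum <- apply(fc, 3, rowSums) - 1          # R x num, diagonal removed
    rsq <- apply(fc^2, 3, rowSums) - 1
    n <- R - 1
    acc <- matrix(0, R, 2)  # running sum of r and pair count per ROI
    for (i in seq_len(num - 1)) for (j in (i + 1):num) {
      sab <- rowSums(fc[, , i] * fc[, , j]) - 1
      cov <- sab - rsum[, i] * rsum[, j] / n
      va <- rsq[, i] - rsum[, i]^2 / n
      vb <- rsq[, j] - rsum[, j]^2 / n
      ok <- va > 1e-14 & vb > 1e-14
      r <- ifelse(ok, cov / sqrt(va * vb), NA_real_)
      acc[ok, 1] <- acc[ok, 1] + r[ok]
      acc[ok, 2] <- acc[ok, 2] + 1
    }
    nPairs <- num * (num - 1) / 2
    v <- ifelse(acc[, 2] >= nPairs / 2, 1 - acc[, 1] / acc[, 2], NA_real_)
    out <- v[ks]
  } else {
    out <- vapply(ks, function(kk) {
      X <- t(fc[kk, -kk, , drop = TRUE])       # num x (R-1)
      if (is.null(dim(X))) X <- matrix(X, nrow = num)
      res <- meanPairCorr(X)
      if (is.na(res$value)) NA_real_ else 1 - res$value
    }, numeric(1))
  }
  names(out) <- if (!is.null(dimnames(x@fc)[[1]]))
    dimnames(x@fc)[[1]][ks] else paste0("roi", ks)
  if (!is.null(k) && length(k) == 1) unname(out) else out
})

#' @describeIn VariabilityProfile-class For a \linkS4class{WindowFcStack}:
#'   intra-network temporal variability V_m = 1 minus the mean pairwise
#'   Pearson correlation, across windows, of the vectorised strict upper
#'   triangle of the members x members FC block. Requires at least 3 member
#'   ROIs (a 2-ROI block vectorises to a single value, which carries no
#'   correlatable pattern); smaller networks return NA.
#' @param members integer vector of ROI indices forming the network
#' @export
setMethod("intraNetworkVariability", "WindowFcStack", function(x, members) {
  members <- as.integer(members)
  if (length(members) < 3) return(NA_real_)
  num <- dim(x@fc)[3]
  if (num < 2) stop("need at least 2 windows")
  ut <- upper.tri(matrix(0, length(members), length(members)))
  X <- t(apply(x@fc[members, members, , drop = FALSE], 3,
               function(b) b[ut]))
  res <- meanPairCorr(X)
  if (is.na(res$value)) NA_real_ else 1 - res$value
})

#' @describeIn VariabilityProfile-class For a \linkS4class{WindowFcStack}:
#'   inter-network temporal variability V_{m-n} = 1 minus the mean pairwise
#'   Pearson correlation, across windows, of the vectorised |m| x |n|
#'   cross-block of the FC matrix. Symmetric in the two networks.
#' @param membersM,membersN disjoint integer index sets of the two networks
#' @export
setMethod("interNetworkVariability", "WindowFcStack",
          function(x, membersM, membersN) {
  membersM <- as.integer(membersM)
  membersN <- as.integer(membersN)
  if (length(intersect(membersM, membersN)))
    stop("network member sets overlap; networks must be a partition")
  if (length(membersM) * length(membersN) < 2) return(NA_real_)
  num <- dim(x@fc)[3]
  if (num < 2) stop("need at least 2 windows")
  X <- t(apply(x@fc[membersM, membersN, , drop = FALSE], 3, as.vector))
  res <- meanPairCorr(X)
  if (is.na(res$value)) NA_real_ else 1 - res$value
})

#' Multi-scale temporal variability of FC
#'
#' The package's central computation. For every window length l in the
#' scheme and every start offset s = 1, ..., l - 1, the series is segmented
#' into non-overlapping l-volume windows, a windowed Pearson FC matrix is
#' computed per window, and the regional, intra-network and inter-network
#' variability statistics (one minus the mean between-window correlation of
#' the vectorised FC pattern) are evaluated. The final profile is the
#' unweighted arithmetic mean of each statistic over all retained
#' (l, s) segmentations; segmentations with fewer than
#' \code{minWindows} full windows are skipped. With the default scheme
#' (l = 21..30) and 240 analysed volumes, 245 segmentations are averaged.
#'
#' @param ts a \linkS4class{RoiTimeSeries} (already preprocessed)
#' @param parcellation a \linkS4class{Parcellation}; its ROI count must
#'   match the series columns
#' @param scheme a \linkS4class{WindowScheme} (default \code{windowScheme()})
#' @param fisherZ apply Fisher r-to-z to FC values first (default FALSE)
#' @return a \linkS4class{VariabilityProfile}
#' @examples
#' set.seed(1)
#' p <- newParcellation(paste0("r", 1:8), rep(c("A", "B"), each = 4))
#' ts <- roiTimeSeries(matrix(rnorm(120 * 8), 120, 8), tr = 2)
#' multiscaleVariability(ts, p, windowScheme(21:24))
#' @export
multiscaleVariability <- function(ts, parcellation,
                                  scheme = windowScheme(),
                                  fisherZ = FALSE) {
  stopifnot(is(ts, "RoiTimeSeries"), is(parcellation, "Parcellation"),
            is(scheme, "WindowScheme"))
  R <- ncol(ts@data)
  if (R != nRoi(parcellation))
    stop("series has ", R, " ROIs but the parcellation has ",
         nRoi(parcellation))
  Tn <- nrow(ts@data)
  nets <- networkNames(parcellation)
  M <- length(nets)
  members <- lapply(nets, function(nm) networkMembers(parcellation, nm))
  pairIdx <- if (M >= 2) utils::combn(M, 2) else
    matrix(integer(0), nrow = 2)
  nPairs <- ncol(pairIdx)
  pairNames <- if (nPairs) paste0(nets[pairIdx[1, ]], "__",
                                  nets[pairIdx[2, ]]) else character(0)

  regS <- regC <- numeric(R)
  intS <- intC <- numeric(M)
  interS <- interC <- numeric(nPairs)
  used <- 0L
  skipped <- 0L

  for (l in scheme@lengths) {
    for (s in seq_len(l - 1L)) {
      num <- (Tn - s + 1L) %/% l
      if (num < scheme@minWindows) next
      stack <- windowFcStack(ts, l, s, fisherZ = fisherZ)
      used <- used + 1L

      vr <- regionalVariability(stack)
      ok <- !is.na(vr)
      regS[ok] <- regS[ok] + vr[ok]
      regC[ok] <- regC[ok] + 1
      skipped <- skipped + sum(!ok)

      for (m in seq_len(M)) {
        v <- intraNetworkVariability(stack, members[[m]])
        if (!is.na(v)) { intS[m] <- intS[m] + v; intC[m] <- intC[m] + 1 }
        else if (length(members[[m]]) >= 3) skipped <- skipped + 1L
      }
      for (q in seq_len(nPairs)) {
        v <- interNetworkVariability(stack, members[[pairIdx[1, q]]],
                                     members[[pairIdx[2, q]]])
        if (!is.na(v)) { interS[q] <- interS[q] + v; interC[q] <- interC[q] + 1 }
        else skipped <- skipped + 1L
      }
    }
  }
  if (used == 0L)
    stop("no valid segmentation: series too short for the window scheme")

  fin <- function(s, n) ifelse(n > 0, s / n, NA_real_)
  new("VariabilityProfile",
      regional = stats::setNames(fin(regS, regC), roiLabels(parcellation)),
      intra    = stats::setNames(fin(intS, intC), nets),
      inter    = stats::setNames(fin(interS, interC), pairNames),
      nSegmentationsUsed = used,
      skippedPairs = skipped)
}

#' @describeIn VariabilityProfile-class accessor: the per-ROI values.
#' @export
setMethod("regionalVariability", "VariabilityProfile",
          function(x) x@regional)

#' @describeIn VariabilityProfile-class accessor: the per-network values.
#' @export
setMethod("intraNetworkVariability", "VariabilityProfile",
          function(x) x@intra)

#' @describeIn VariabilityProfile-class accessor: the per-network-pair
#'   values.
#' @export
setMethod("interNetworkVariability", "VariabilityProfile",
          function(x) x@inter)

setMethod("show", "VariabilityProfile", function(object) {
  cat("VariabilityProfile:", length(object@regional), "regional,",
      length(object@intra), "intra-network,", length(object@inter),
      "inter-network values;", object@nSegmentationsUsed,
      "segmentations averaged\n")
  cat("  regional range:",
      paste(signif(range(object@regional, na.rm = TRUE), 4),
            collapse = " - "), "\n")
})

#' Flatten a VariabilityProfile into one feature row
#'
#' Produces the wide one-row representation used in the cohort feature
#' table: columns \code{regional_<roi>}, \code{intra_<network>},
#' \code{inter_<netA>__<netB>} (network pairs in lexicographic order) and
#' \code{n_segmentations_used}.
#'
#' @param x a \linkS4class{VariabilityProfile}
#' @return a one-row data.frame
#' @export
flattenProfile <- function(x) {
  stopifnot(is(x, "VariabilityProfile"))
  inter <- x@inter
  if (length(inter)) {
    parts <- strsplit(names(inter), "__", fixed = TRUE)
    nm <- vapply(parts, function(p)
      paste(sort(p), collapse = "__"), character(1))
    names(inter) <- nm
    inter <- inter[order(names(inter))]
  }
  out <- c(stats::setNames(x@regional, paste0("regional_", names(x@regional))),
           stats::setNames(x@intra, paste0("intra_", names(x@intra))),
           stats::setNames(inter, paste0("inter_", names(inter))),
           n_segmentations_used = x@nSegmentationsUsed)
  as.data.frame(as.list(out), check.names = FALSE)
}
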