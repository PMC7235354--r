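#' @import methods
NULL

#' Parcellation: ROI labels and their network assignment
#'
#' An ordered set of region-of-interest (ROI) labels together with the
#' assignment of each ROI to exactly one named functional network. The row
#' order of the source config file is the canonical column order of every
#' ROI time-series matrix analysed against this parcellation; the network
#' blocks define the intra- and inter-network FC sub-matrices.
#'
#' @slot roiLabels character vector of ROI names (length R, no duplicates).
#' @slot networks character vector, same length, the network of each ROI.
#' @slot networkNames character vector of distinct network names, in order
#'   of first appearance.
#'
#' @seealso [loadParcellation()], [networkMembers()]
#' @export
setClass("Parcellation",
  representation(
    roiLabels    = "character",
    networks     = "character",
    networkNames = "character"
  )
)

setValidity("Parcellation", function(object) {
  msg <- character()
  R <- length(object@roiLabels)
  if (R < 2) msg <- c(msg, "a parcellation needs at least 2 ROIs")
  if (length(object@networks) != R)
    msg <- c(msg, "roiLabels and networks must have equal length")
  dup <- object@roiLabels[duplicated(object@roiLabels)]
  if (length(dup))
    msg <- c(msg, paste0("duplicate ROI label(s): ",
                         paste(unique(dup), collapse = ", ")))
  if (any(!nzchar(object@networks)) || anyNA(object@networks))
    msg <- c(msg, paste0("ROI(s) with empty network assignment: ",
                         paste(object@roiLabels[!nzchar(object@networks) |
                                                is.na(object@networks)],
                               collapse = ", ")))
  if (anyDuplicated(object@networkNames))
    msg <- c(msg, "networkNames contains duplicates")
  if (!setequal(object@networkNames, unique(object@networks)))
    msg <- c(msg, "networkNames must equal the set of assigned networks")
  if (length(msg)) msg else TRUE
})

#' One subject's parcellated BOLD time series
#'
#' A real-valued T x R matrix of ROI signals (rows = time points / volumes,
#' columns = ROIs) plus the sampling interval (repetition time) in seconds.
#'
#' @slot data numeric matrix, T rows x R columns; column names are ROI labels.
#' @slot tr repetition time in seconds (e.g. 2 for TR = 2,000 ms).
#' @slot subjectId subject identifier.
#' @export
setClass("RoiTimeSeries",
  representation(
    data      = "matrix",
    tr        = "numeric",
    subjectId = "character"
  )
)

setValidity("RoiTimeSeries", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) msg <- c(msg, "data must be numeric")
  if (nrow(object@data) < 2) msg <- c(msg, "need at least 2 time points")
  if (anyNA(object@data) || any(!is.finite(object@data)))
    msg <- c(msg, "data contains missing or non-finite values")
  if (length(object@tr) != 1 || !is.finite(object@tr) || object@tr <= 0)
    msg <- c(msg, "tr must be a single positive number (seconds)")
  if (length(msg)) msg else TRUE
})

#' Rigid-body head-motion trace with framewise displacement
#'
#' Six realignment parameters per volume (3 translations in mm, 3 rotations
#' in radians) and the derived framewise displacement (FD) series: per frame,
#' the sum of absolute backward differences of the translations plus the
#' rotation differences converted to arc length on a sphere of the given
#' head radius. The first frame has FD 0 by convention.
#'
#' @slot params numeric matrix, T x 6 (tx, ty, tz, rx, ry, rz).
#' @slot fd numeric vector of per-frame FD in mm, fd[1] == 0.
#' @slot meanFd arithmetic mean of fd, in mm.
#' @slot headRadius sphere radius (mm) used for the rotation conversion.
#' @export
setClass("MotionTrace",
  representation(
    params     = "matrix",
    fd         = "numeric",
    meanFd     = "numeric",
    headRadius = "numeric"
  )
)

setValidity("MotionTrace", function(object) {
  msg <- character()
  if (ncol(object@params) != 6) msg <- c(msg, "params must have 6 columns")
  if (any(!is.finite(object@params)))
    msg <- c(msg, "params contains non-finite values")
  if (length(object@fd) != nrow(object@params))
    msg <- c(msg, "fd length must match number of frames")
  if (any(object@fd < 0)) msg <- c(msg, "fd must be non-negative")
  if (length(object@fd) &&
      !isTRUE(all.equal(object@meanFd, mean(object@fd))))
    msg <- c(msg, "meanFd must equal mean(fd)")
  if (length(msg)) msg else TRUE
})

#' Multi-scale window scheme for dynamic FC
#'
#' The grid of window lengths (in volumes) over which windowed FC is
#' computed. For each length l every start offset s = 1, ..., l - 1 defines
#' one non-overlapping segmentation of the series; segmentations yielding
#' fewer than \code{minWindows} full windows are skipped.
#'
#' @slot lengths integer vector of window lengths in volumes (default 21:30,
#'   i.e. 42-60 s at TR = 2 s).
#' @slot minWindows minimum number of full windows a segmentation must
#'   produce to be retained (default 2).
#' @export
setClass("WindowScheme",
  representation(
    lengths    = "integer",
    minWindows = "integer"
  )
)

setValidity("WindowScheme", function(object) {
  msg <- character()
  if (!length(object@lengths) || any(object@lengths < 2))
    msg <- c(msg, "every window length must be >= 2 volumes")
  if (object@minWindows < 2)
    msg <- c(msg, "minWindows must be >= 2 (variability needs window pairs)")
  if (length(msg)) msg else TRUE
})

#' Stack of windowed FC matrices for one segmentation
#'
#' The sequence of R x R Pearson correlation matrices computed in the
#' non-overlapping, equal-length windows of a single (length, offset)
#' segmentation, stored as an R x R x num array in temporal order.
#'
#' @slot fc numeric array, R x R x num; each slice symmetric with unit
#'   diagonal, entries in [-1, 1] or NA where a ROI was constant within the
#'   window.
#' @slot starts integer vector of 1-based window start indices.
#' @slot windowLength window length in volumes.
#' @export
setClass("WindowFcStack",
  representation(
    fc           = "array",
    starts       = "integer",
    windowLength = "integer"
  )
)

setValidity("WindowFcStack", function(object) {
  msg <- character()
  d <- dim(object@fc)
  if (length(d) != 3 || d[1] != d[2])
    msg <- c(msg, "fc must be an R x R x num array")
  if (length(object@starts) != d[3])
    msg <- c(msg, "starts length must equal the number of windows")
  if (is.unsorted(object@starts, strictly = TRUE))
    msg <- c(msg, "windows must be in temporal order")
  if (object@windowLength < 2) msg <- c(msg, "windowLength must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Per-subject temporal-variability profile
#'
#' The multi-scale averaged temporal variability of FC patterns: one value
#' per ROI (regional), one per network (intra-network; NA where the network
#' has fewer than 3 ROIs, whose FC block carries no correlatable pattern),
#' and one per unordered network pair (inter-network). Every defined value
#' lies in [0, 2]: 0 means the windowed FC pattern is perfectly stable, 2
#' perfectly anticorrelated across windows.
#'
#' @slot regional named numeric, one value per ROI.
#' @slot intra named numeric, one value per network (NA allowed).
#' @slot inter named numeric, one value per unordered network pair, names
#'   "netA__netB" with the pair in parcellation network order.
#' @slot nSegmentationsUsed number of (length, offset) segmentations that
#'   entered the multi-scale average.
#' @slot skippedPairs total count of undefined statistic evaluations
#'   (constant pattern vectors, degenerate blocks) skipped during the
#'   multi-scale average.
#' @export
setClass("VariabilityProfile",
  representation(
    regional           = "numeric",
    intra              = "numeric",
    inter              = "numeric",
    nSegmentationsUsed = "integer",
    skippedPairs       = "integer"
  )
)

setValidity("VariabilityProfile", function(object) {
  msg <- character()
  vals <- c(object@regional, object@intra, object@inter)
  ok <- is.na(vals) | (vals >= -1e-8 & vals <= 2 + 1e-8)
  if (!all(ok))
    msg <- c(msg, "defined variability values must lie in [0, 2]")
  if (object@nSegmentationsUsed < 0)
    msg <- c(msg, "nSegmentationsUsed must be non-negative")
  if (length(msg)) msg else TRUE
})
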