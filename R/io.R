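#' Constructors and accessors for time-series and motion objects
#'
#' @param data numeric T x R matrix (rows = volumes, columns = ROIs)
#' @param tr repetition time in seconds
#' @param subjectId subject identifier
#' @return a \linkS4class{RoiTimeSeries}
#' @export
roiTimeSeries <- function(data, tr = 2, subjectId = "subject") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  new("RoiTimeSeries", data = data, tr = tr,
      subjectId = as.character(subjectId))
}

#' @rdname RoiTimeSeries-class
#' @export
setMethod("seriesData", "RoiTimeSeries", function(x) x@data)

#' @rdname RoiTimeSeries-class
#' @export
setMethod("repetitionTime", "RoiTimeSeries", function(x) x@tr)

#' @rdname RoiTimeSeries-class
#' @export
setMethod("subjectId", "RoiTimeSeries", function(x) x@subjectId)

#' @rdname RoiTimeSeries-class
#' @export
setMethod("nVolumes", "RoiTimeSeries", function(x) nrow(x@data))

setMethod("show", "RoiTimeSeries", function(object) {
  cat("RoiTimeSeries '", object@subjectId, "': ", nrow(object@data),
      " volumes x ", ncol(object@data), " ROIs, TR = ", object@tr, " s\n",
      sep = "")
})

#' @rdname MotionTrace-class
#' @export
setMethod("framewiseDisplacement", "MotionTrace", function(x) x@fd)

#' @rdname MotionTrace-class
#' @export
setMethod("meanFd", "MotionTrace", function(x) x@meanFd)

setMethod("show", "MotionTrace", function(object) {
  cat("MotionTrace: ", nrow(object@params), " frames, mean FD = ",
      signif(object@meanFd, 4), " mm (head radius ", object@headRadius,
      " mm)\n", sep = "")
})

#' Read a ROI time-series TSV
#'
#' Expects T rows x R columns, tab-separated, one header line of ROI labels.
#' When a \linkS4class{Parcellation} is given, the column labels must match
#' its ROI order exactly (checked by label checksum).
#'
#' @param path file path
#' @param tr repetition time in seconds
#' @param subjectId subject identifier (default: file name stem)
#' @param parcellation optional \linkS4class{Parcellation} to validate
#'   column order against
#' @return a \linkS4class{RoiTimeSeries}
#' @export
readRoiTimeSeries <- function(path, tr = 2,
                              subjectId = sub("\\.[^.]*$", "", basename(path)),
                              parcellation = NULL) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(d)
  storage.mode(m) <- "double"
  if (!is.null(parcellation)) {
    if (!identical(parcellationChecksum(colnames(m)),
                   parcellationChecksum(parcellation)))
      stop("ROI columns of ", path,
           " do not match the parcellation ROI order")
  }
  roiTimeSeries(m, tr = tr, subjectId = subjectId)
}

#' Write a ROI time-series TSV
#'
#' @param x a \linkS4class{RoiTimeSeries}
#' @param path output path
#' @return `path`, invisibly
#' @export
writeRoiTimeSeries <- function(x, path) {
  utils::write.table(format(x@data, digits = 10, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 6-column motion-parameter TSV
#'
#' Expects T rows x 6 columns (tx, ty, tz in mm; rx, ry, rz in radians),
#' with or without a header line.
#'
#' @param path file path
#' @param headRadius sphere radius in mm for the rotation-to-arc-length
#'   conversion (default 50)
#' @return a \linkS4class{MotionTrace}
#' @export
readMotionTrace <- function(path, headRadius = 50) {
  first <- readLines(path, n = 1)
  has_header <- any(is.na(suppressWarnings(
    as.numeric(strsplit(first, "\t")[[1]]))))
  d <- utils::read.delim(path, header = has_header, sep = "\t")
  m <- as.matrix(d)
  storage.mode(m) <- "double"
  motionTrace(m, headRadius = headRadius)
}

#' Write a motion trace TSV
#'
#' @param x a \linkS4class{MotionTrace}
#' @param path output path
#' @return `path`, invisibly
#' @export
writeMotionTrace <- function(x, path) {
  m <- x@params
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  utils::write.table(format(m, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
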