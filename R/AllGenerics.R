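#' @rdname Parcellation-class
#' @param object,x a \linkS4class{Parcellation}
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))

#' @rdname Parcellation-class
#' @export
setGeneric("networkNames", function(x) standardGeneric("networkNames"))

#' @rdname Parcellation-class
#' @export
setGeneric("nRoi", function(x) standardGeneric("nRoi"))

#' @rdname Parcellation-class
#' @param network a network name
#' @export
setGeneric("networkMembers", function(x, network)
  standardGeneric("networkMembers"))

#' @rdname RoiTimeSeries-class
#' @param x a \linkS4class{RoiTimeSeries}
#' @export
setGeneric("seriesData", function(x) standardGeneric("seriesData"))

#' @rdname RoiTimeSeries-class
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))

#' @rdname RoiTimeSeries-class
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname RoiTimeSeries-class
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))

#' @rdname MotionTrace-class
#' @param x a \linkS4class{MotionTrace}
#' @export
setGeneric("framewiseDisplacement", function(x)
  standardGeneric("framewiseDisplacement"))

#' @rdname MotionTrace-class
#' @export
setGeneric("meanFd", function(x) standardGeneric("meanFd"))

#' @rdname VariabilityProfile-class
#' @param x a \linkS4class{VariabilityProfile}
#' @export
setGeneric("regionalVariability", function(x, ...)
  standardGeneric("regionalVariability"))

#' @rdname VariabilityProfile-class
#' @export
setGeneric("intraNetworkVariability", function(x, ...)
  standardGeneric("intraNetworkVariability"))

#' @rdname VariabilityProfile-class
#' @export
setGeneric("interNetworkVariability", function(x, ...)
  standardGeneric("interNetworkVariability"))
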