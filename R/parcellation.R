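#' Load a ROI-to-network parcellation config
#'
#' Reads the table that assigns every region of interest (ROI) to one named
#' network. Two formats are accepted: tab-separated text with a header line
#' and columns \code{roi_label} and \code{network} (an optional leading ROI
#' index column is ignored), or a JSON object mapping ROI label to network
#' name. The file row order becomes the canonical ROI order: every time
#' series matrix analysed against the parcellation must have its columns in
#' this order.
#'
#' The packaged default (\code{system.file("extdata",
#' "aal116_networks.tsv", package = "tvfc")}) covers the 116 ROIs of the
#' AAL atlas assigned to 11 networks -- sensorimotor, visual, auditory,
#' default-mode, frontoparietal, cingulo-opercular, salience, attention,
#' subcortical, thalamus and cerebellum -- with the thalamus and cerebellum
#' treated as standalone networks. The assignment is a best-effort editable
#' approximation constructed for this package, not a published lookup
#' table: replace the file to use your own scheme.
#'
#' @param path path to the config file; default is the packaged AAL-116
#'   table.
#' @return a \linkS4class{Parcellation}.
#' @examples
#' p <- loadParcellation()
#' nRoi(p)           # 116
#' networkNames(p)   # 11 networks
#' @export
loadParcellation <- function(path = system.file("extdata",
                                                "aal116_networks.tsv",
                                                package = "tvfc")) {
  if (!file.exists(path)) stop("parcellation config not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("reading a JSON parcellation requires the jsonlite package")
    m <- jsonlite::fromJSON(path)
    if (!is.list(m) || is.null(names(m)))
      stop("JSON parcellation must be an object mapping ROI label to network")
    lab <- names(m)
    net <- vapply(m, function(v) as.character(v)[1], character(1))
  } else {
    d <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           check.names = FALSE)
    cols <- tolower(names(d))
    i_lab <- match(TRUE, cols %in% c("roi_label", "roi", "label"))
    i_net <- match(TRUE, cols %in% c("network", "net"))
    if (is.na(i_lab) || is.na(i_net))
      stop("unknown column layout in ", path,
           ": header line must name columns 'roi_label' and 'network', got: ",
           paste(names(d), collapse = ", "))
    lab <- d[[i_lab]]
    net <- d[[i_net]]
  }
  newParcellation(lab, net)
}

#' Construct a Parcellation from label and network vectors
#'
#' @param roiLabels character vector of ROI names, in canonical order.
#' @param networks character vector of same length: network of each ROI.
#' @return a validated \linkS4class{Parcellation}.
#' @export
newParcellation <- function(roiLabels, networks) {
  roiLabels <- as.character(roiLabels)
  networks <- as.character(networks)
  networks[is.na(networks)] <- ""
  bad <- roiLabels[!nzchar(networks)]
  if (length(bad))
    stop("ROI(s) with empty network assignment: ",
         paste(bad, collapse = ", "))
  dup <- unique(roiLabels[duplicated(roiLabels)])
  if (length(dup))
    stop("duplicate ROI label(s): ", paste(dup, collapse = ", "))
  new("Parcellation", roiLabels = roiLabels, networks = networks,
      networkNames = unique(networks))
}

#' Write a parcellation back to its TSV config format
#'
#' @param x a \linkS4class{Parcellation}
#' @param path output file path
#' @return `path`, invisibly.
#' @export
writeParcellation <- function(x, path) {
  stopifnot(is(x, "Parcellation"))
  utils::write.table(
    data.frame(roi_label = x@roiLabels, network = x@networks),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname Parcellation-class
#' @export
setMethod("roiLabels", "Parcellation", function(x) x@roiLabels)

#' @rdname Parcellation-class
#' @export
setMethod("networkNames", "Parcellation", function(x) x@networkNames)

#' @rdname Parcellation-class
#' @export
setMethod("nRoi", "Parcellation", function(x) length(x@roiLabels))

#' @describeIn Parcellation-class indices (ascending, 1-based) of the ROIs
#'   belonging to one network. Over all networks these index sets partition
#'   1..R.
#' @export
setMethod("networkMembers", "Parcellation", function(x, network) {
  if (!network %in% x@networkNames)
    stop("unknown network '", network, "'; valid networks: ",
         paste(x@networkNames, collapse = ", "))
  which(x@networks == network)
})

#' Short checksum of the ROI label order
#'
#' Used in manifests and run logs to guard against column-order mismatch
#' between a parcellation and a time-series file.
#'
#' @param x a \linkS4class{Parcellation} or a character vector of labels
#' @return a character scalar checksum.
#' @export
parcellationChecksum <- function(x) {
  lab <- if (is(x, "Parcellation")) x@roiLabels else as.character(x)
  s <- paste(lab, collapse = "\x1f")
  # 31-bit polynomial rolling hash; dependency-free, stable across platforms
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

setMethod("show", "Parcellation", function(object) {
  cat("Parcellation with", length(object@roiLabels), "ROIs in",
      length(object@networkNames), "networks\n")
  sizes <- table(factor(object@networks, levels = object@networkNames))
  cat(paste0("  ", names(sizes), " (", as.integer(sizes), ")",
             collapse = "\n"), "\n")
  cat("ROI-order checksum:", parcellationChecksum(object), "\n")
})
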