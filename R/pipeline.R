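#' Default run configuration
#'
#' The zero-argument configuration reproduces the conventional analysis
#' defaults: discard 10 initial volumes, Friston-24 + band-pass 0.01-0.10 Hz
#' without global signal regression, mean-FD exclusion strictly above
#' 0.2 mm, window lengths 21-30 volumes with all start offsets, ANCOVA gate
#' at p < 0.05 with Bonferroni-corrected post-hoc contrasts.
#'
#' @param outputDir output directory
#' @param dataDir directory holding the cohort (manifest.tsv plus series
#'   and motion TSVs); ignored when \code{simulate} is given
#' @param simulate optional [simulationSpec()] -- the cohort is generated
#'   into \code{dataDir} first
#' @param parcellation optional path to a parcellation config; default: a
#'   synthetic even split for simulated data, the packaged AAL-116 table
#'   otherwise
#' @param seed integer seed recorded and used for any simulation
#' @return a config list of class \code{RunConfig}
#' @export
runConfig <- function(outputDir, dataDir = file.path(outputDir, "data"),
                      simulate = NULL, parcellation = NULL, seed = 1) {
  cfg <- list(
    paths = list(outputDir = outputDir, dataDir = dataDir,
                 parcellation = parcellation),
    simulate = simulate,
    preprocess = list(nDiscard = 10, low = 0.01, high = 0.10,
                      gsr = FALSE, fdThreshold = 0.2),
    windows = list(lengths = 21:30, minWindows = 2),
    fisherZ = FALSE,
    stats = list(gateAlpha = 0.05, alpha = 0.05, fdr = FALSE),
    covariates = c("age", "sex", "education", "mean_fd"),
    scores = c("illness_duration", "cpz_equiv", "saps", "sans", "hamd",
               "ymrs", "wais_i", "wais_ds"),
    seed = as.integer(seed))
  class(cfg) <- "RunConfig"
  cfg
}

#' Read / write a RunConfig as YAML
#'
#' @param path YAML file path
#' @return for `readRunConfig`, a \code{RunConfig}; for `writeRunConfig`,
#'   `path` invisibly
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- runConfig(outputDir = raw$paths$outputDir)
  for (nm in intersect(names(raw), names(cfg))) {
    if (is.list(cfg[[nm]]) && is.list(raw[[nm]])) {
      for (k in names(raw[[nm]])) cfg[[nm]][[k]] <- raw[[nm]][[k]]
    } else cfg[[nm]] <- raw[[nm]]
  }
  if (!is.null(raw$simulate))
    cfg$simulate <- do.call(simulationSpec, raw$simulate)
  class(cfg) <- "RunConfig"
  cfg
}

#' @rdname readRunConfig
#' @param cfg a \code{RunConfig}
#' @export
writeRunConfig <- function(cfg, path) {
  out <- unclass(cfg)
  if (!is.null(out$simulate)) out$simulate <- unclass(out$simulate)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' simulate (optional) -> motion QC -> per-subject preprocessing ->
#' multi-scale FC variability -> group statistics and clinical
#' correlations. Writes, into the output directory: \code{qc_report.tsv},
#' \code{features.tsv} (one row per kept subject), \code{group_stats.tsv}
#' (ANCOVA main effects with post-hoc pairwise columns),
#' \code{clinical_correlations.tsv}, the verbatim config
#' (\code{run_config.yaml}) and a run log (\code{run_log.yaml}) with
#' package version, parcellation checksum and undefined-value counts.
#' Re-running an identical config reproduces identical tables. Undefined
#' variability values are written as NA, never imputed.
#'
#' @param cfg a [runConfig()] (or a path to a YAML config)
#' @return invisibly, a list with the in-memory tables and the output dir
#' @export
runPipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  stopifnot(inherits(cfg, "RunConfig"))
  outDir <- cfg$paths$outputDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(cfg$simulate)) {
    spec <- cfg$simulate
    simulateCohort(spec, dir = cfg$paths$dataDir)
  }
  manifestPath <- file.path(cfg$paths$dataDir, "manifest.tsv")
  if (!file.exists(manifestPath))
    stop("cohort manifest not found: ", manifestPath)
  manifest <- utils::read.delim(manifestPath, sep = "\t",
                                check.names = FALSE)

  # parcellation: explicit path > synthetic split (simulated) > AAL default
  firstSeries <- file.path(cfg$paths$dataDir, manifest$series_file[1])
  nRoiData <- ncol(utils::read.delim(firstSeries, nrows = 1))
  parc <- if (!is.null(cfg$paths$parcellation)) {
    loadParcellation(cfg$paths$parcellation)
  } else if (!is.null(cfg$simulate)) {
    syntheticParcellation(nRoiData, nNetworks = min(3, nRoiData))
  } else loadParcellation()
  if (nRoi(parc) != nRoiData)
    stop("parcellation has ", nRoi(parc), " ROIs but series files have ",
         nRoiData)

  # motion QC
  motions <- lapply(seq_len(nrow(manifest)), function(i)
    readMotionTrace(file.path(cfg$paths$dataDir, manifest$motion_file[i])))
  names(motions) <- manifest$subject_id
  qc <- qcExclude(motions, threshold = cfg$preprocess$fdThreshold)
  kept <- qc$subject_id[qc$kept]

  # per-subject preprocessing + variability
  scheme <- windowScheme(cfg$windows$lengths, cfg$windows$minWindows)
  rows <- vector("list", length(kept))
  skippedTotal <- 0L
  for (i in seq_along(kept)) {
    sid <- kept[i]
    mi <- match(sid, manifest$subject_id)
    ts <- readRoiTimeSeries(
      file.path(cfg$paths$dataDir, manifest$series_file[mi]),
      tr = if (!is.null(cfg$simulate)) cfg$simulate$tr else 2,
      subjectId = sid)
    if (nrow(ts@data) <= cfg$preprocess$nDiscard)
      stop("subject ", sid, ": series shorter than the discard count")
    clean <- preprocessSubject(ts, motions[[sid]],
                               nDiscard = cfg$preprocess$nDiscard,
                               low = cfg$preprocess$low,
                               high = cfg$preprocess$high,
                               gsr = isTRUE(cfg$preprocess$gsr))
    prof <- multiscaleVariability(clean, parc, scheme,
                                  fisherZ = isTRUE(cfg$fisherZ))
    skippedTotal <- skippedTotal + prof@skippedPairs
    rows[[i]] <- cbind(subject_id = sid, flattenProfile(prof))
  }
  features <- do.call(rbind, rows)

  # group statistics on kept subjects
  mi <- match(features$subject_id, manifest$subject_id)
  group <- manifest$group[mi]
  covNames <- intersect(cfg$covariates, names(manifest))
  covs <- manifest[mi, covNames, drop = FALSE]
  featCols <- setdiff(names(features), c("subject_id",
                                         "n_segmentations_used"))
  gs <- groupStats(features[featCols], group, covs,
                   gateAlpha = cfg$stats$gateAlpha, alpha = cfg$stats$alpha,
                   fdr = isTRUE(cfg$stats$fdr))
  statsTab <- gs$main
  if (nrow(gs$pairwise)) {
    for (q in seq_len(nrow(unique(gs$pairwise[c("group1", "group2")])))) {
      pr <- unique(gs$pairwise[c("group1", "group2")])[q, ]
      tag <- paste0(pr$group1, "_vs_", pr$group2)
      sub <- gs$pairwise[gs$pairwise$group1 == pr$group1 &
                           gs$pairwise$group2 == pr$group2, ]
      statsTab[[paste0("p_raw_", tag)]] <-
        sub$p_raw[match(statsTab$feature, sub$feature)]
      statsTab[[paste0("p_bonf_", tag)]] <-
        sub$p_bonferroni[match(statsTab$feature, sub$feature)]
      statsTab[[paste0("sig_", tag)]] <-
        sub$significant[match(statsTab$feature, sub$feature)]
    }
  }

  scoreNames <- intersect(cfg$scores, names(manifest))
  corrTab <- if (length(scoreNames))
    clinicalCorrelations(manifest[mi, scoreNames, drop = FALSE],
                         features[featCols], group) else
    data.frame()

  writeTsv <- function(d, f) utils::write.table(
    d, file.path(outDir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  writeTsv(qc, "qc_report.tsv")
  writeTsv(features, "features.tsv")
  writeTsv(statsTab, "group_stats.tsv")
  writeTsv(corrTab, "clinical_correlations.tsv")
  writeRunConfig(cfg, file.path(outDir, "run_config.yaml"))
  yaml::write_yaml(list(
    package = "tvfc",
    version = as.character(utils::packageVersion("tvfc")),
    r_version = R.version.string,
    parcellation_checksum = parcellationChecksum(parc),
    n_subjects = nrow(manifest), n_kept = length(kept),
    n_excluded = nrow(manifest) - length(kept),
    skipped_undefined_values = skippedTotal,
    step_order = "discard -> nuisance regression -> band-pass",
    seed = cfg$seed), file.path(outDir, "run_log.yaml"))

  invisible(list(qc = qc, features = features, groupStats = statsTab,
                 correlations = corrTab, parcellation = parc,
                 outputDir = outDir))
}
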