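# Run expr under a fixed RNG state, restoring the caller's state after.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

#' Random correlation matrix with a target mean off-diagonal
#'
#' Builds a full-rank random correlation structure (normalised Wishart-type
#' factor product) and shrinks it towards the all-ones matrix so the
#' average off-diagonal correlation is approximately \code{baseCor}.
#' Positive definite for any \code{baseCor} in [0, 1).
#'
#' @param R dimension
#' @param baseCor target mean off-diagonal correlation (default 0.2)
#' @return an R x R correlation matrix
#' @export
randomCorrMatrix <- function(R, baseCor = 0.2) {
  stopifnot(baseCor >= 0, baseCor < 1)
  W <- matrix(stats::rnorm(R * R), R, R)
  S <- tcrossprod(W) + diag(R) * R * 0.1
  D <- 1 / sqrt(diag(S))
  C <- S * tcrossprod(D)
  out <- (1 - baseCor) * C + baseCor
  diag(out) <- 1
  out
}

#' Simulation specification for a synthetic cohort
#'
#' Defines a three-group cohort of zero-mean multivariate Gaussian BOLD-like
#' series whose inter-regional covariance alternates between two regimes.
#' With per-ROI mixing weight lambda_k(t) = w(t) * a for modulated ROIs (0
#' elsewhere, w(t) a square wave), the series is
#' x_k(t) = sqrt(1 - lambda_k(t)) u_k(t) + sqrt(lambda_k(t)) v_k(t) with
#' u ~ N(0, Sigma_A), v ~ N(0, Sigma_B) independent, plus white noise.
#' This realises the regime blend (1 - w a) Sigma_A + w a Sigma_B on the
#' modulated block while keeping the time-varying covariance positive
#' definite for every a in [0, 1] by construction. The group amplitude a is
#' the planted "amount of FC dynamics"; a = 0 gives a stationary series.
#'
#' Defaults mirror a typical clinical resting-state acquisition: 116 ROIs,
#' 250 volumes at TR = 2 s, three groups of 66/53/66 subjects.
#'
#' @param R ROI count (default 116)
#' @param T volumes per subject, pre-discard (default 250)
#' @param tr repetition time, seconds (default 2)
#' @param nPerGroup named integer vector of subjects per group
#' @param baseCor mean off-diagonal of the stationary correlation (0.2)
#' @param modulatedRois indices of ROIs whose covariance is modulated
#' @param modulationAmplitude per-group blend amplitude a in [0, 1]
#'   (same names/order as nPerGroup)
#' @param amplitudeJitter SD of per-subject jitter added to the group
#'   amplitude (clipped to [0, 1]; default 0.05)
#' @param regimePeriod square-wave period in volumes (default 40,
#'   incommensurate with window lengths 21-30)
#' @param sinusoidal use a raised-cosine rather than square regime wave
#' @param noiseSd additive white-noise SD (default 0.2)
#' @param ageRange,educationRange uniform covariate ranges (years)
#' @param motionFdLog meanlog/sdlog of the lognormal per-subject target
#'   mean FD in mm (default log(0.08), 0.4)
#' @param highMotionSubjects cohort-level subject indices forced to
#'   \code{highMotionFd}
#' @param highMotionFd target mean FD for forced high movers (default 0.3)
#' @param clinicalScore name of the score linked to the planted amplitude
#' @param clinicalScoreRho target Spearman correlation between that score
#'   and the per-subject true amplitude (default 0.3)
#' @param seed integer seed; the cohort is a pure function of the spec
#' @return a validated list of class \code{SimulationSpec}
#' @export
simulationSpec <- function(R = 116, T = 250, tr = 2,
                           nPerGroup = c(schizophrenia = 66, bipolar = 53,
                                         control = 66),
                           baseCor = 0.2,
                           modulatedRois = seq_len(min(10, R)),
                           modulationAmplitude = c(schizophrenia = 0.6,
                                                   bipolar = 0.3,
                                                   control = 0),
                           amplitudeJitter = 0.05,
                           regimePeriod = 40, sinusoidal = FALSE,
                           noiseSd = 0.2,
                           ageRange = c(18, 45), educationRange = c(6, 20),
                           motionFdLog = c(log(0.08), 0.4),
                           highMotionSubjects = integer(0),
                           highMotionFd = 0.3,
                           clinicalScore = "sans",
                           clinicalScoreRho = 0.3,
                           seed = 1) {
  if (is.null(names(nPerGroup)))
    names(nPerGroup) <- paste0("group", seq_along(nPerGroup))
  if (is.null(names(modulationAmplitude)) ||
      (!all(names(nPerGroup) %in% names(modulationAmplitude)) &&
       length(modulationAmplitude) == length(nPerGroup)))
    names(modulationAmplitude) <- names(nPerGroup)
  stopifnot(R >= 2, T >= 4, tr > 0, length(nPerGroup) >= 1,
            all(nPerGroup >= 1),
            all(modulationAmplitude >= 0), all(modulationAmplitude <= 1),
            all(modulatedRois >= 1), all(modulatedRois <= R),
            regimePeriod >= 2, noiseSd >= 0,
            abs(clinicalScoreRho) <= 1)
  if (!all(names(nPerGroup) %in% names(modulationAmplitude)))
    stop("modulationAmplitude must name every group")
  spec <- list(R = as.integer(R), T = as.integer(T), tr = tr,
               nPerGroup = nPerGroup, baseCor = baseCor,
               modulatedRois = as.integer(modulatedRois),
               modulationAmplitude = modulationAmplitude,
               amplitudeJitter = amplitudeJitter,
               regimePeriod = as.integer(regimePeriod),
               sinusoidal = isTRUE(sinusoidal), noiseSd = noiseSd,
               ageRange = ageRange, educationRange = educationRange,
               motionFdLog = motionFdLog,
               highMotionSubjects = as.integer(highMotionSubjects),
               highMotionFd = highMotionFd,
               clinicalScore = clinicalScore,
               clinicalScoreRho = clinicalScoreRho,
               seed = as.integer(seed))
  class(spec) <- "SimulationSpec"
  spec
}

#' @export
print.SimulationSpec <- function(x, ...) {
  cat("SimulationSpec:", x$R, "ROIs x", x$T, "volumes, TR =", x$tr, "s\n")
  cat("  groups:", paste0(names(x$nPerGroup), "=", x$nPerGroup,
                          " (a=", x$modulationAmplitude[names(x$nPerGroup)],
                          ")", collapse = ", "), "\n")
  cat("  modulated ROIs:", length(x$modulatedRois),
      "| regime period:", x$regimePeriod, "volumes | seed:", x$seed, "\n")
  invisible(x)
}

# Cohort-level covariance regimes, a pure function of the spec seed.
regimeCovariances <- function(spec) {
  withSeed(spec$seed, {
    list(A = randomCorrMatrix(spec$R, spec$baseCor),
         B = randomCorrMatrix(spec$R, spec$baseCor))
  })
}

# Mixture covariance for per-ROI weights lambda (vector length R).
blendCovariance <- function(SigmaA, SigmaB, lambda) {
  a <- sqrt(1 - lambda)
  b <- sqrt(lambda)
  out <- SigmaA * tcrossprod(a) + SigmaB * tcrossprod(b)
  diag(out) <- 1
  out
}

#' Simulate one subject's series and motion trace
#'
#' @param spec a [simulationSpec()]
#' @param group group name (must appear in \code{spec$nPerGroup})
#' @param subjectSeed integer seed for this subject's draws
#' @param subjectId identifier written into the objects
#' @param targetFd optional target mean FD in mm, overriding the spec's
#'   lognormal draw
#' @return list with \code{ts} (\linkS4class{RoiTimeSeries}),
#'   \code{motion} (\linkS4class{MotionTrace}), \code{trueAmplitude},
#'   \code{targetFd}
#' @export
simulateSubject <- function(spec, group, subjectSeed,
                            subjectId = paste0("sub-", subjectSeed),
                            targetFd = NULL) {
  stopifnot(inherits(spec, "SimulationSpec"))
  if (!group %in% names(spec$nPerGroup))
    stop("unknown group '", group, "'")
  reg <- regimeCovariances(spec)
  aGroup <- spec$modulationAmplitude[[group]]
  withSeed(subjectSeed, {
    a <- min(1, max(0, aGroup + stats::rnorm(1, 0, spec$amplitudeJitter)))
    lambda1 <- numeric(spec$R)
    lambda1[spec$modulatedRois] <- a
    t_idx <- seq_len(spec$T)
    if (spec$sinusoidal) {
      w <- (1 - cos(2 * pi * (t_idx - 1) / spec$regimePeriod)) / 2
    } else {
      half <- spec$regimePeriod / 2
      w <- ((t_idx - 1) %/% half) %% 2
    }
    # distinct regime weights are few (2 for the square wave); factor once
    uw <- sort(unique(w))
    chols <- lapply(uw, function(ww) {
      S <- blendCovariance(reg$A, reg$B, ww * lambda1)
      ch <- tryCatch(chol(S), error = function(e)
        stop("blended covariance not positive definite at regime weight ",
             signif(ww, 3)))
      ch
    })
    Z <- matrix(stats::rnorm(spec$T * spec$R), spec$T, spec$R)
    X <- matrix(0, spec$T, spec$R)
    for (i in seq_along(uw)) {
      rows <- which(w == uw[i])
      X[rows, ] <- Z[rows, , drop = FALSE] %*% chols[[i]]
    }
    if (spec$noiseSd > 0)
      X <- X + matrix(stats::rnorm(spec$T * spec$R, 0, spec$noiseSd),
                      spec$T, spec$R)
    colnames(X) <- paste0("roi", seq_len(spec$R))
    if (is.null(targetFd))
      targetFd <- stats::rlnorm(1, spec$motionFdLog[1], spec$motionFdLog[2])
    steps <- cbind(matrix(stats::rnorm(spec$T * 3, 0, 0.02), spec$T, 3),
                   matrix(stats::rnorm(spec$T * 3, 0, 4e-4), spec$T, 3))
    params <- apply(steps, 2, cumsum)
    mfd <- mean(computeFd(params, 50))
    if (mfd > 0) params <- params * (targetFd / mfd)
    list(ts = roiTimeSeries(X, tr = spec$tr, subjectId = subjectId),
         motion = motionTrace(params, headRadius = 50),
         trueAmplitude = a, targetFd = targetFd)
  })
}

# Deterministic per-subject seed below 2^31, derived from the spec seed.
subjectSeedFor <- function(specSeed, index) {
  (as.double(specSeed) * 48271 + index * 16807) %% 2147483647
}

#' Simulate and write a full cohort
#'
#' Writes one series TSV and one motion TSV per subject, a cohort manifest
#' (group, covariates, clinical scores, file paths) and a ground-truth table
#' (per-subject true modulation amplitude and target mean FD). The linked
#' clinical score is generated as a monotone function of the subject's true
#' amplitude plus calibrated noise, so its Spearman correlation with the
#' amplitude approximates \code{spec$clinicalScoreRho}; remaining scores are
#' plausible group-dependent fillers (patient-only where appropriate).
#'
#' @param spec a [simulationSpec()]
#' @param dir output directory (created if needed)
#' @param writeFiles write TSVs? (FALSE returns objects only)
#' @return invisibly, a list with \code{manifest}, \code{groundTruth},
#'   \code{subjects} (per-subject ts/motion objects), \code{dir}
#' @export
simulateCohort <- function(spec, dir = NULL, writeFiles = !is.null(dir)) {
  stopifnot(inherits(spec, "SimulationSpec"))
  if (writeFiles) {
    if (is.null(dir)) stop("dir required to write files")
    ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
    if (!ok || file.access(dir, 2) != 0)
      stop("output directory not writable: ", dir)
  }
  groups <- rep(names(spec$nPerGroup), times = spec$nPerGroup)
  n <- length(groups)
  ids <- sprintf("sub-%03d", seq_len(n))
  subjects <- vector("list", n)
  trueAmp <- targetFd <- numeric(n)
  for (i in seq_len(n)) {
    tf <- if (i %in% spec$highMotionSubjects) spec$highMotionFd else NULL
    subjects[[i]] <- simulateSubject(spec, groups[i],
                                     subjectSeedFor(spec$seed, i),
                                     subjectId = ids[i], targetFd = tf)
    trueAmp[i] <- subjects[[i]]$trueAmplitude
    targetFd[i] <- subjects[[i]]$targetFd
  }
  names(subjects) <- ids

  cov_and_scores <- withSeed(spec$seed + 7, {
    age <- round(stats::runif(n, spec$ageRange[1], spec$ageRange[2]))
    sex <- sample(c("male", "female"), n, replace = TRUE)
    edu <- round(stats::runif(n, spec$educationRange[1],
                              spec$educationRange[2]))
    # latent for the amplitude-linked score: Pearson rho on Gaussian ranks
    # chosen so the Spearman correlation approximates the requested target
    rhoS <- spec$clinicalScoreRho
    rhoP <- 2 * sin(pi * rhoS / 6)
    ampZ <- if (isTRUE(stats::sd(trueAmp) > 0)) scale(trueAmp)[, 1] else
      stats::rnorm(n)
    latent <- rhoP * ampZ + sqrt(1 - rhoP^2) * stats::rnorm(n)
    linked <- round(pmax(0, 40 + 12 * latent), 1)
    patient <- groups != names(spec$nPerGroup)[length(spec$nPerGroup)]
    scores <- data.frame(
      illness_duration = ifelse(patient,
                                round(stats::rgamma(n, 2, 1 / 20), 1), NA),
      cpz_equiv = ifelse(patient, round(stats::rgamma(n, 3, 1 / 100)), NA),
      saps = ifelse(patient, round(pmax(0, stats::rnorm(n, 18, 8))), NA),
      sans = round(pmax(0, stats::rnorm(n, 20, 9))),
      hamd = round(pmax(0, stats::rnorm(n, 6, 4))),
      ymrs = round(pmax(0, stats::rnorm(n, 4, 3))),
      wais_i = round(stats::rnorm(n, 75, 15)),
      wais_ds = round(stats::rnorm(n, 72, 15)))
    scores[[spec$clinicalScore]] <- linked
    list(age = age, sex = sex, edu = edu, scores = scores)
  })

  meanFdObs <- vapply(subjects, function(s) meanFd(s$motion), numeric(1))
  manifest <- cbind(
    data.frame(subject_id = ids, group = groups,
               age = cov_and_scores$age, sex = cov_and_scores$sex,
               education = cov_and_scores$edu,
               mean_fd = unname(meanFdObs)),
    cov_and_scores$scores)
  groundTruth <- data.frame(subject_id = ids, group = groups,
                            true_amplitude = trueAmp,
                            target_mean_fd = targetFd)

  if (writeFiles) {
    manifest$series_file <- paste0(ids, "_series.tsv")
    manifest$motion_file <- paste0(ids, "_motion.tsv")
    for (i in seq_len(n)) {
      writeRoiTimeSeries(subjects[[i]]$ts,
                         file.path(dir, manifest$series_file[i]))
      writeMotionTrace(subjects[[i]]$motion,
                       file.path(dir, manifest$motion_file[i]))
    }
    utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(groundTruth, file.path(dir, "ground_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(manifest = manifest, groundTruth = groundTruth,
                 subjects = subjects, dir = if (writeFiles) dir else NULL))
}

#' Evenly split R ROIs into named synthetic networks
#'
#' Convenience parcellation for simulated data: ROIs roi1..roiR assigned
#' round-robin-free (contiguous blocks) to \code{nNetworks} networks.
#'
#' @param R ROI count
#' @param nNetworks number of networks (default 3)
#' @return a \linkS4class{Parcellation}
#' @export
syntheticParcellation <- function(R, nNetworks = 3) {
  stopifnot(R >= nNetworks)
  sizes <- diff(round(seq(0, R, length.out = nNetworks + 1)))
  nets <- rep(paste0("net", seq_len(nNetworks)), times = sizes)
  newParcellation(paste0("roi", seq_len(R)), nets)
}

#' Randomised stress suite of variability values
#'
#' Generates \code{nInputs} seeded random multivariate series of varying
#' size (8-20 ROIs, 50-300 volumes) and modulation amplitude, computes the
#' full multi-scale variability profile of each with the default window
#' scheme, and returns every defined regional, intra-network and
#' inter-network value. Used to exercise the statistic across its input
#' space; all defined values must lie in [0, 2].
#'
#' @param nInputs number of random series (default 50)
#' @param seed base seed; input i uses a seed derived from it
#' @return numeric vector of all defined variability values
#' @export
stressSuiteValues <- function(nInputs = 50, seed = 1) {
  vals <- c()
  for (i in seq_len(nInputs)) {
    si <- (as.double(seed) * 1000 + i) %% 2147483647
    dims <- withSeed(si, list(R = sample(8:20, 1),
                              Tn = sample(50:300, 1),
                              a = stats::runif(1)))
    sp <- simulationSpec(R = dims$R, T = dims$Tn,
                         nPerGroup = c(g = 1),
                         modulatedRois = seq_len(max(2, dims$R %/% 3)),
                         modulationAmplitude = c(g = dims$a),
                         seed = si)
    s <- simulateSubject(sp, "g", si + 1)
    p <- syntheticParcellation(dims$R, 3)
    prof <- multiscaleVariability(s$ts, p)
    v <- c(regionalVariability(prof), intraNetworkVariability(prof),
           interNetworkVariability(prof))
    vals <- c(vals, v[!is.na(v)])
  }
  unname(vals)
}
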