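## Class-conditional synthetic EEG with a planted microstate structure.
## Test scaffolding with known ground truth: a piecewise-constant latent
## state sequence over four dipolar prototype topographies, band-specific
## amplitude-modulated sinusoid carriers, and class effects (AD: alpha
## attenuation + Poisson delta bursts; FTD: frontally-weighted delta bursts
## locked to Class-C periods; HC: none).

runWithSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(expr)
}

subjectSeed <- function(seed, index) {
  ((as.numeric(seed) %% 2147483647) * 10007 + index * 7919) %% 2147483629 + 1
}

bandCenter <- function(b) sqrt(prod(BAND_GRID[[b]]))   # geometric mean Hz

#' Canonical microstate prototype topographies
#'
#' Builds the four canonical class geometries on a montage: A, a
#' right-anterior to left-posterior diagonal dipole; B, the mirrored
#' left-anterior to right-posterior diagonal; C, an anterior-posterior
#' midline gradient; D, a symmetric posterior/parietal focal pattern. Maps
#' are channel-mean-zero and unit-norm, with pairwise absolute spatial
#' correlation below 0.9.
#'
#' @param montage data.frame with columns channel, x, y
#'   (default \code{\link{montage1020}}).
#' @return 4 x N matrix, rows named A-D, columns named by channel.
#' @export
makePrototypes <- function(montage = montage1020()) {
  if (!all(c("channel", "x", "y") %in% names(montage)))
    stop("montage must provide channel, x, y")
  if (anyNA(montage$x) || anyNA(montage$y))
    stop("montage positions missing for some channels")
  x <- montage$x; y <- montage$y
  maps <- rbind(
    A = x + y,
    B = y - x,
    C = y,
    D = exp(-((x - 0)^2 + (y + 0.6)^2) / (2 * 0.35^2)))
  colnames(maps) <- montage$channel
  normalizeMaps(maps)
}

#' Cohort specification for the synthetic generator
#'
#' Bundles cohort sizes, recording parameters and class-conditional effect
#' sizes. Three profiles are provided: \code{"default"} (moderate,
#' physiologically plausible effects), \code{"strong"} (pronounced effects
#' and low noise, for end-to-end separability runs) and \code{"null"} (all
#' class effects disabled; every class shares one generative process, for
#' leakage/chance-level audits).
#'
#' @param nPerClass named counts, e.g. \code{c(AD = 4, FTD = 4, HC = 4)}.
#' @param durationS recording length per subject in seconds.
#' @param rate sampling rate in Hz.
#' @param seed cohort master seed; per-subject seeds are derived from it.
#' @param profile effect-size profile (see above).
#' @param ... override any field of the returned spec.
#' @return list of class \code{CohortSpec}.
#' @export
cohortSpec <- function(nPerClass = c(AD = 4, FTD = 4, HC = 4),
                       durationS = 40, rate = 256, seed = 42,
                       profile = c("default", "strong", "null"), ...) {
  profile <- match.arg(profile)
  spec <- list(
    nPerClass = nPerClass, durationS = durationS, rate = rate, seed = seed,
    profile = profile,
    noiseSd = 0.10,
    segmentMs = c(60, 120),
    bandAmps = c(delta = 0.35, theta = 0.45, alpha = 1.0,
                 beta = 0.25, gamma = 0.12),
    alphaAttenuation = 0.3,     # AD alpha amplitude factor
    deltaBurstRate = 12,        # AD bursts / minute
    burstDurS = 0.3,
    burstGain = 4,
    ftdBurstRate = 12,          # FTD bursts / minute, locked to Class-C periods
    ftdFrontalGain = 4)
  if (profile == "strong") {
    spec$alphaAttenuation <- 0.1
    spec$deltaBurstRate <- 20
    spec$burstGain <- 6
    spec$ftdBurstRate <- 20
    spec$ftdFrontalGain <- 6
  } else if (profile == "null") {
    spec$alphaAttenuation <- 1
    spec$deltaBurstRate <- 0
    spec$ftdBurstRate <- 0
  }
  dots <- list(...)
  spec[names(dots)] <- dots
  if (any(spec$nPerClass < 0)) stop("counts must be >= 0")
  if (spec$rate <= 0) stop("rate must be positive")
  if (spec$noiseSd < 0 || spec$burstGain < 0 || spec$ftdFrontalGain < 0)
    stop("effect sizes must be >= 0")
  class(spec) <- "CohortSpec"
  spec
}

## piecewise-constant latent state path; segment lengths uniform in segmentMs
latentSequence <- function(nSamples, rate, segmentMs) {
  labels <- integer(0)
  cur <- sample.int(4, 1)
  while (length(labels) < nSamples) {
    durMs <- stats::runif(1, segmentMs[1], segmentMs[2])
    len <- max(1L, round(durMs / 1000 * rate))
    labels <- c(labels, rep(cur, len))
    cur <- sample((1:4)[-cur], 1)
  }
  labels[seq_len(nSamples)]
}

hannWindow <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

#' Simulate one subject's EEG with planted microstate ground truth
#'
#' The signal is a sum over bands of an amplitude-modulated sinusoid carrier
#' (at the band's geometric-mean frequency) times the prototype topography
#' of the current latent state, plus spatially white Gaussian noise. Class
#' effects: AD attenuates the alpha carrier (lowering alpha-band SNR against
#' the noise floor, i.e. fragmenting the alpha correlation trajectories) and
#' adds Poisson-timed delta-frequency bursts carrying a diffuse
#' vertex-centred topography; FTD adds frontally-weighted Class-C delta
#' bursts locked to Class-C periods; HC adds none. Deterministic given
#' \code{seed}.
#'
#' @param classLabel "AD", "FTD" or "HC".
#' @param spec a \code{\link{cohortSpec}}.
#' @param seed subject RNG seed.
#' @param subjectId subject identifier.
#' @param montage montage table (default \code{\link{montage1020}}).
#' @return list with \code{recording} (\linkS4class{Recording}) and
#'   \code{groundTruth}: state sequence (A-D per sample), segment durations
#'   in ms, the per-band template maps used, and the class label.
#' @export
simulateSubject <- function(classLabel, spec = cohortSpec(), seed = 1,
                            subjectId = "sub-001", montage = montage1020()) {
  if (!classLabel %in% c("AD", "FTD", "HC"))
    stop("unknown class label: ", classLabel)
  rate <- spec$rate
  n <- round(spec$durationS * rate)
  if (n < 1) stop("duration too short")
  proto <- makePrototypes(montage)
  nCh <- ncol(proto)
  runWithSeed(seed, {
    stateIdx <- latentSequence(n, rate, spec$segmentMs)
    tt <- (seq_len(n) - 1) / rate
    bands <- names(spec$bandAmps)
    amps <- spec$bandAmps
    if (classLabel == "AD") amps["alpha"] <- amps["alpha"] * spec$alphaAttenuation
    coef <- numeric(n)
    for (b in bands) {
      f <- bandCenter(b)
      env <- 1 + 0.5 * sin(2 * pi * 0.3 * tt + stats::runif(1, 0, 2 * pi))
      coef <- coef + amps[[b]] * env * sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi))
    }
    X <- t(proto[stateIdx, , drop = FALSE] * coef)   # channels x samples

    burstLen <- max(2L, round(spec$burstDurS * rate))
    win <- hannWindow(burstLen)
    fDelta <- bandCenter("delta")
    addBurst <- function(X, center, topo, gain) {
      i0 <- max(1L, center - burstLen %/% 2L)
      i1 <- min(n, i0 + burstLen - 1L)
      idx <- i0:i1
      w <- win[seq_along(idx)]
      osc <- sin(2 * pi * fDelta * tt[idx] + stats::runif(1, 0, 2 * pi))
      X[, idx] <- X[, idx] + topo %o% (gain * w * osc)
      X
    }
    if (classLabel == "AD" && spec$deltaBurstRate > 0) {
      ## diffuse vertex-centred slow-wave topography: the burst intrudes a
      ## spatial pattern distinct from every canonical class, the
      ## correlation-domain signature of cortical disconnection
      topoDiffuse <- exp(-(montage$x^2 + montage$y^2) / (2 * 0.8^2))
      topoDiffuse <- topoDiffuse - mean(topoDiffuse)
      topoDiffuse <- topoDiffuse / sqrt(sum(topoDiffuse^2))
      nb <- stats::rpois(1, spec$deltaBurstRate * spec$durationS / 60)
      centers <- sort(sample.int(n, min(nb, n)))
      for (cen in centers)
        X <- addBurst(X, cen, topoDiffuse, spec$burstGain)
    }
    if (classLabel == "FTD" && spec$ftdBurstRate > 0) {
      cSamples <- which(stateIdx == 3L)               # Class C periods
      if (length(cSamples)) {
        ## burst rate is per minute of recording; events land in C periods.
        ## Topography: the Class-C map shifted into a frontal-focal pattern
        ## (frontotemporal degeneration), C-flavoured but distinct from all
        ## four canonical maps in correlation space
        nb <- stats::rpois(1, spec$ftdBurstRate * spec$durationS / 60)
        topoF <- exp(-(montage$x^2 + (montage$y - 0.95)^2) / (2 * 0.2^2))
        topoF <- topoF - mean(topoF)
        topoF <- topoF / sqrt(sum(topoF^2))
        centers <- sort(sample(cSamples, min(nb, length(cSamples))))
        for (cen in centers)
          X <- addBurst(X, cen, topoF, spec$ftdFrontalGain)
      }
    }
    if (spec$noiseSd > 0)
      X <- X + matrix(stats::rnorm(nCh * n, sd = spec$noiseSd), nCh, n)
    rec <- Recording(X, rate = rate, channels = colnames(proto),
                     subjectId = subjectId, group = classLabel,
                     reference = "synthetic")
    runs <- rle(stateIdx)
    gt <- list(stateSequence = MS_CLASSES[stateIdx],
               segmentDurationsMs = runs$lengths / rate * 1000,
               bandTemplates = stats::setNames(
                 rep(list(proto), length(bands)), bands),
               classLabel = classLabel)
    list(recording = rec, groundTruth = gt)
  })
}

#' Simulate a cohort
#'
#' Generates \code{nPerClass} subjects per class with unique subject ids and
#' deterministic per-subject seeds derived from the cohort seed.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @return list with elements \code{recordings} (list of Recording) and
#'   \code{groundTruths}; subject order is AD, FTD, HC blocks.
#' @export
simulateCohort <- function(spec = cohortSpec()) {
  classes <- rep(names(spec$nPerClass), spec$nPerClass)
  out <- vector("list", length(classes))
  gts <- vector("list", length(classes))
  ids <- sprintf("sub-%03d", seq_along(classes))
  for (i in seq_along(classes)) {
    sim <- simulateSubject(classes[i], spec, seed = subjectSeed(spec$seed, i),
                           subjectId = ids[i])
    out[[i]] <- sim$recording
    gts[[i]] <- sim$groundTruth
  }
  names(out) <- ids
  names(gts) <- ids
  list(recordings = out, groundTruths = gts)
}

#' Write a simulated cohort as a BIDS-like directory
#'
#' EDF per subject under \code{sub-XXX/eeg/}, a run-length-encoded ground
#' truth JSON sidecar, and a cohort-level \code{participants.tsv}.
#'
#' @param cohort result of \code{\link{simulateCohort}}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- character(0)
  for (id in names(cohort$recordings)) {
    rec <- cohort$recordings[[id]]
    gt <- cohort$groundTruths[[id]]
    eegdir <- file.path(dir, id, "eeg")
    dir.create(eegdir, recursive = TRUE, showWarnings = FALSE)
    writeEDF(rec, file.path(eegdir, paste0(id, "_task-rest_eeg.edf")))
    runs <- rle(gt$stateSequence)
    side <- list(classLabel = gt$classLabel,
                 rate = samplingRate(rec),
                 rle = list(values = runs$values, lengths = runs$lengths))
    writeLines(jsonlite::toJSON(side, digits = NA, auto_unbox = TRUE),
               file.path(eegdir, paste0(id, "_groundtruth.json")))
    rows <- c(rows, paste(id, groupLabel(rec), sep = "\t"))
  }
  writeLines(c("participant_id\tGroup", rows),
             file.path(dir, "participants.tsv"))
  invisible(dir)
}
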