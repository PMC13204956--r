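## LOSO orchestration of the full pipeline: per-fold template extraction
## (training subjects only), soft backfitting, two-band fusion, classifier
## training, subject-level majority voting, and the two-stage cascade.

STAGE_BANDS <- list(stage1 = c("alpha", "delta"),
                    stage2 = c("delta", "theta"))

#' Preprocess a cohort for microstate extraction
#'
#' Average re-references, resamples to \code{targetRate}, band-pass filters
#' each required band (plus the broadband anchor), epochs with the sliding
#' window, and pre-computes each epoch's GFP-peak topographies. The result
#' feeds \code{\link{foldTemplates}} and \code{\link{runStage}}.
#'
#' @param recordings list of \linkS4class{Recording} with group labels.
#' @param bands narrowband names needed downstream
#'   (default the union of both stages: alpha, delta, theta).
#' @param targetRate analysis rate in Hz (default 256).
#' @param windowS,stepS epoching window/step in seconds (defaults 10/5).
#' @return object of class \code{PreparedCohort}.
#' @export
prepareCohort <- function(recordings, bands = c("alpha", "delta", "theta"),
                          targetRate = 256, windowS = 10, stepS = 5) {
  allBands <- unique(c("broadband", bands))
  subjects <- vapply(recordings, subjectId, "")
  if (anyDuplicated(subjects)) stop("duplicate subject ids")
  labels <- vapply(recordings, groupLabel, "")
  names(labels) <- subjects
  epochSets <- list()
  peaks <- list()
  for (rec in recordings) {
    sid <- subjectId(rec)
    rec <- rereferenceAverage(rec)
    if (samplingRate(rec) != targetRate)
      rec <- resampleRecording(rec, targetRate)
    perBand <- list()
    perPeaks <- list()
    for (b in allBands) {
      fb <- bandpass(rec, b)
      es <- epochRecording(fb, windowS, stepS)
      es@band <- b
      perBand[[b]] <- es
      pk <- lapply(epochs(es), function(e) {
        g <- gfp(e)
        idx <- detectGfpPeaks(g)
        list(maps = t(e[, idx, drop = FALSE]), gfp = g[idx])
      })
      perPeaks[[b]] <- list(
        maps = do.call(rbind, lapply(pk, `[[`, "maps")),
        gfp = unlist(lapply(pk, `[[`, "gfp")))
    }
    epochSets[[sid]] <- perBand
    peaks[[sid]] <- perPeaks
  }
  structure(list(subjects = subjects, labels = labels, bands = allBands,
                 epochSets = epochSets, peaks = peaks,
                 channels = channelNames(recordings[[1]]),
                 rate = targetRate, windowS = windowS, stepS = stepS),
            class = "PreparedCohort")
}

#' Extract fold templates from an explicit subject allow-list
#'
#' Pools the GFP-peak topographies of the listed training subjects only
#' (the leakage guard: the allow-list is recorded in the audit field),
#' clusters the broadband pool into four templates, assigns canonical A-D
#' labels against the built-in prototypes, then clusters each narrowband
#' pool and Hungarian-aligns it to the broadband anchor.
#'
#' @param prep a \code{\link{prepareCohort}} result.
#' @param trainSubjects subject ids whose data may be used.
#' @param bands narrow bands to extract (default all prepared).
#' @param seed clustering seed.
#' @param maxPeakMaps cap on pooled peak maps per band (random subsample,
#'   seeded; default 3000) to bound clustering cost.
#' @return list with \code{anchor}, \code{templates} (named by band) and
#'   \code{audit} (subjects used).
#' @export
foldTemplates <- function(prep, trainSubjects,
                          bands = setdiff(prep$bands, "broadband"),
                          seed = 42, maxPeakMaps = 3000) {
  stopifnot(inherits(prep, "PreparedCohort"))
  missing_ <- setdiff(trainSubjects, prep$subjects)
  if (length(missing_)) stop("unknown subjects: ", paste(missing_, collapse = ", "))
  pool <- function(band) {
    maps <- do.call(rbind, lapply(trainSubjects,
                                  function(s) prep$peaks[[s]][[band]]$maps))
    g <- unlist(lapply(trainSubjects,
                       function(s) prep$peaks[[s]][[band]]$gfp))
    if (nrow(maps) > maxPeakMaps) {
      keep <- runWithSeed(seed, sample.int(nrow(maps), maxPeakMaps))
      maps <- maps[keep, , drop = FALSE]
      g <- g[keep]
    }
    list(maps = maps, gfp = g)
  }
  bb <- pool("broadband")
  anchor <- modifiedKmeans(bb$maps, K = 4, seed = seed, gfpValues = bb$gfp,
                           band = "broadband", channels = prep$channels)
  anchor <- labelCanonical(anchor)
  templates <- list()
  for (b in bands) {
    nb <- pool(b)
    ts <- modifiedKmeans(nb$maps, K = 4, seed = seed + 1, gfpValues = nb$gfp,
                         band = b, channels = prep$channels)
    templates[[b]] <- alignBands(ts, anchor)
  }
  list(anchor = anchor, templates = templates,
       audit = list(subjects = sort(trainSubjects), bands = bands))
}

## Backfit and fuse one subject's epochs for a stage's band pair.
fuseSubject <- function(prep, templates, subject, stage, label = NA) {
  bands <- STAGE_BANDS[[stage]]
  es1 <- prep$epochSets[[subject]][[bands[1]]]
  es2 <- prep$epochSets[[subject]][[bands[2]]]
  lapply(seq_len(nEpochs(es1)), function(k) {
    s1 <- backfitSoft(epochs(es1)[[k]], templates$templates[[bands[1]]],
                      subjectId = subject, epochIndex = k)
    s2 <- backfitSoft(epochs(es2)[[k]], templates$templates[[bands[2]]],
                      subjectId = subject, epochIndex = k)
    fuseBands(s1, s2, stage = stage, label = label)
  })
}

stageLabel <- function(labels, stage) {
  if (stage == "stage1") ifelse(labels == "HC", "HC", "dementia")
  else labels
}

stagePositive <- function(stage) if (stage == "stage1") "dementia" else "FTD"

#' Run one cascade stage under leave-one-subject-out evaluation
#'
#' For every fold: fold templates are extracted from the fold's training
#' subjects only, all subjects are backfitted and fused with those
#' templates, a fresh classifier is trained (train vs validation subjects
#' disjoint), the held-out subject's epochs are predicted and aggregated by
#' majority vote. Stage 1 screens dementia vs HC on the alpha+delta fusion
#' over all subjects; stage 2 differentiates AD vs FTD on the delta+theta
#' fusion over patient subjects.
#'
#' @param prep a \code{\link{prepareCohort}} result.
#' @param stage "stage1" or "stage2".
#' @param modelCfg a \code{\link{modelConfig}} (nClasses forced to 2).
#' @param trainCfg a \code{\link{trainConfig}}.
#' @param seed orchestration seed (fold splits, clustering, model init).
#' @param subjects subjects to include; stage 2 defaults to AD/FTD only.
#' @param maxPeakMaps see \code{\link{foldTemplates}}.
#' @param verbose print per-fold progress.
#' @return list of class \code{StageResult}: per-subject predictions
#'   (data.frame), \code{report} (confusion, balanced accuracy, recalls,
#'   AUC + Youden threshold) and \code{audit} (per-fold template subject
#'   lists and split composition).
#' @export
runStage <- function(prep, stage = c("stage1", "stage2"),
                     modelCfg = modelConfig(), trainCfg = trainConfig(),
                     seed = 42, subjects = NULL, maxPeakMaps = 3000,
                     verbose = FALSE) {
  stage <- match.arg(stage)
  stopifnot(inherits(prep, "PreparedCohort"))
  if (is.null(subjects)) {
    subjects <- if (stage == "stage2")
      prep$subjects[prep$labels %in% c("AD", "FTD")] else prep$subjects
  }
  labels <- stageLabel(prep$labels[subjects], stage)
  names(labels) <- subjects
  positive <- stagePositive(stage)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("stage requires exactly two classes; got: ",
                                 paste(classes, collapse = ", "))
  modelCfg$nClasses <- 2
  folds <- makeLosoSplits(subjects, labels, trainCfg$valFraction, seed)
  preds <- data.frame(subject = character(0), truth = character(0),
                      predicted = character(0), posProb = numeric(0),
                      nEpochs = integer(0), stringsAsFactors = FALSE)
  audit <- list()
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    tmpl <- foldTemplates(prep, fold$train, bands = STAGE_BANDS[[stage]],
                          seed = seed + fi, maxPeakMaps = maxPeakMaps)
    fuse <- function(subs) {
      out <- list()
      for (s in subs) out <- c(out, fuseSubject(prep, tmpl, s, stage,
                                                label = labels[s]))
      out
    }
    trX <- fuse(fold$train)
    vaX <- fuse(fold$val)
    teX <- fuseSubject(prep, tmpl, fold$test, stage)
    lab <- function(xs) vapply(xs, function(f) f@label, "")
    model <- buildModel(modelCfg, seed = seed + 1000 + fi)
    ## fixed class order (negative, positive): locale-proof unit mapping
    model <- trainModel(model, trX, lab(trX), vaX, lab(vaX), trainCfg,
                        classes = c(setdiff(classes, positive), positive))
    P <- predictEpochs(model, teX)
    votes <- colnames(P)[max.col(P, ties.method = "first")]
    final <- majorityVote(votes, P, positive = positive)
    preds <- rbind(preds, data.frame(
      subject = fold$test, truth = labels[fold$test], predicted = final,
      posProb = mean(P[, positive]), nEpochs = nrow(P),
      stringsAsFactors = FALSE))
    audit[[fi]] <- list(fold = fi, test = fold$test,
                        templateSubjects = tmpl$audit$subjects,
                        train = fold$train, val = fold$val,
                        bestEpoch = model$bestEpoch)
    if (verbose)
      message(sprintf("[%s fold %d/%d] test=%s truth=%s pred=%s p(%s)=%.3f",
                      stage, fi, length(folds), fold$test, labels[fold$test],
                      final, positive, mean(P[, positive])))
  }
  conf <- confusionMatrix(preds$truth, preds$predicted, classes)
  roc <- rocAucYouden(preds$posProb, preds$truth == positive)
  report <- list(confusion = conf,
                 balancedAccuracy = balancedAccuracy(conf),
                 recalls = diag(as.matrix(conf)) / rowSums(conf),
                 auc = roc$auc, youden = roc)
  structure(list(stage = stage, predictions = preds, report = report,
                 audit = audit, positive = positive),
            class = "StageResult")
}

#' Run the full two-stage cascade
#'
#' Stage 1 (dementia screening) over all subjects and stage 2 (AD vs FTD)
#' over the true patients, both LOSO. Final 3-class labels compose the two
#' stages per subject via \code{\link{cascadePredict}}; healthy subjects
#' that stage 1 falsely flags are subtyped by a stage-2 model trained on
#' all patients (leakage-free for those subjects, which never enter patient
#' training data). Also reports the screening/subtyping composition metric:
#' the mean of the stage-1 HC recall and the stage-2 AD and FTD recalls.
#'
#' @param prep a \code{\link{prepareCohort}} result.
#' @param modelCfg,trainCfg model and training configuration.
#' @param seed orchestration seed.
#' @param maxPeakMaps see \code{\link{foldTemplates}}.
#' @param verbose print per-fold progress.
#' @return list of class \code{CascadeResult}: \code{stage1}, \code{stage2}
#'   (StageResults), \code{predictions} (subject, truth, 3-class label),
#'   \code{confusion}, \code{balancedAccuracy3}, and
#'   \code{compositionBalancedAccuracy}.
#' @export
runCascade <- function(prep, modelCfg = modelConfig(),
                       trainCfg = trainConfig(), seed = 42,
                       maxPeakMaps = 3000, verbose = FALSE) {
  s1 <- runStage(prep, "stage1", modelCfg, trainCfg, seed = seed,
                 maxPeakMaps = maxPeakMaps, verbose = verbose)
  s2 <- runStage(prep, "stage2", modelCfg, trainCfg, seed = seed,
                 maxPeakMaps = maxPeakMaps, verbose = verbose)
  subjects <- s1$predictions$subject
  stage2Lab <- stats::setNames(s2$predictions$predicted,
                               s2$predictions$subject)
  ## subtype stage-1 false positives with an all-patient stage-2 model
  fp <- subjects[s1$predictions$predicted == "dementia" &
                   !(subjects %in% names(stage2Lab))]
  if (length(fp)) {
    patients <- prep$subjects[prep$labels %in% c("AD", "FTD")]
    patLab <- prep$labels[patients]
    split <- runWithSeed(seed + 5000, {
      val <- unlist(lapply(unique(patLab), function(cl) {
        pool <- patients[patLab == cl]
        sample(pool, max(1, round(trainCfg$valFraction * length(pool))))
      }), use.names = FALSE)
      list(train = setdiff(patients, val), val = val)
    })
    tmpl <- foldTemplates(prep, split$train, bands = STAGE_BANDS$stage2,
                          seed = seed + 7000, maxPeakMaps = maxPeakMaps)
    fuse <- function(subs, withLab = TRUE) {
      out <- list()
      for (s in subs) out <- c(out, fuseSubject(
        prep, tmpl, s, "stage2",
        label = if (withLab) prep$labels[s] else NA))
      out
    }
    trX <- fuse(split$train); vaX <- fuse(split$val)
    lab <- function(xs) vapply(xs, function(f) f@label, "")
    mdl <- buildModel(modelCfg, seed = seed + 9000)
    mdl <- trainModel(mdl, trX, lab(trX), vaX, lab(vaX), trainCfg,
                      classes = c("AD", "FTD"))
    for (s in fp) {
      P <- predictEpochs(mdl, fuse(s, withLab = FALSE))
      votes <- colnames(P)[max.col(P, ties.method = "first")]
      stage2Lab[s] <- majorityVote(votes, P, positive = "FTD")
    }
  }
  finalLab <- cascadePredict(s1$predictions$predicted,
                             ifelse(subjects %in% names(stage2Lab),
                                    stage2Lab[subjects], NA))
  truth3 <- prep$labels[subjects]
  conf3 <- confusionMatrix(truth3, finalLab, c("AD", "FTD", "HC"))
  comp <- mean(c(s1$report$recalls["HC"],
                 s2$report$recalls["AD"], s2$report$recalls["FTD"]))
  structure(list(stage1 = s1, stage2 = s2,
                 predictions = data.frame(subject = subjects, truth = truth3,
                                          stage1 = s1$predictions$predicted,
                                          stage2 = unname(
                                            stage2Lab[subjects]),
                                          final = finalLab,
                                          stringsAsFactors = FALSE),
                 confusion = conf3,
                 balancedAccuracy3 = balancedAccuracy(conf3),
                 compositionBalancedAccuracy = comp),
            class = "CascadeResult")
}
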