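#' Leave-one-subject-out fold splits
#'
#' One fold per subject: all of that subject's epochs form the test set and
#' the remaining subjects are split into training and validation subject
#' sets (8:2 by default), stratified by class. When any remaining class has
#' a single subject, stratification degenerates: a warning is issued and an
#' unstratified split is used for that fold. Deterministic given
#' \code{seed}.
#'
#' @param subjects subject ids.
#' @param labels class label per subject.
#' @param valFraction validation fraction of the non-test subjects.
#' @param seed RNG seed.
#' @return list of folds, each \code{list(test, train, val)} of subject ids.
#' @export
makeLosoSplits <- function(subjects, labels, valFraction = 0.2, seed = 42) {
  if (length(subjects) < 3) stop("need >= 3 subjects")
  labels <- as.character(labels)
  names(labels) <- subjects
  if (length(unique(labels)) < 2) stop("need >= 2 classes")
  runWithSeed(seed, {
    lapply(seq_along(subjects), function(i) {
      test <- subjects[i]
      rem <- subjects[-i]
      remLab <- labels[rem]
      counts <- table(remLab)
      if (any(counts < 2)) {
        warning("class with a single remaining subject: unstratified split",
                call. = FALSE)
        nVal <- max(1, round(valFraction * length(rem)))
        val <- sample(rem, nVal)
      } else {
        val <- unlist(lapply(names(counts), function(cl) {
          pool <- rem[remLab == cl]
          nVal <- min(length(pool) - 1, max(1, round(valFraction * length(pool))))
          sample(pool, nVal)
        }), use.names = FALSE)
      }
      list(test = test, train = setdiff(rem, val), val = val)
    })
  })
}

#' Subject-level majority vote
#'
#' The modal epoch-level label wins; ties are broken by the higher mean
#' predicted probability among the tied classes, and a residual exact tie
#' goes to the disease-positive class.
#'
#' @param votes character vector of per-epoch predicted labels.
#' @param probs optional epochs x classes probability matrix (columns named
#'   by class) for the tie-break.
#' @param positive disease-positive class label for the residual tie-break.
#' @return the final subject label.
#' @export
majorityVote <- function(votes, probs = NULL, positive = NULL) {
  if (!length(votes)) stop("empty votes")
  counts <- table(votes)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1) return(top)
  if (!is.null(probs)) {
    mp <- colMeans(probs[, top, drop = FALSE])
    best <- top[mp == max(mp)]
    if (length(best) == 1) return(best)
    top <- best
  }
  if (!is.null(positive) && positive %in% top) return(positive)
  sort(top)[1]
}

#' Balanced accuracy from a confusion matrix
#'
#' Arithmetic mean of the per-class recalls (rows = true classes).
#'
#' @param confusion square counts matrix, rows true, columns predicted.
#' @return balanced accuracy in [0, 1].
#' @export
balancedAccuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  rs <- rowSums(confusion)
  if (any(rs == 0)) stop("empty true-class row in confusion matrix")
  mean(diag(confusion) / rs)
}

confusionMatrix <- function(truth, predicted, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  table(factor(truth, classes), factor(predicted, classes))
}

#' ROC AUC and Youden-optimal threshold
#'
#' AUC by the rank (Mann-Whitney) statistic with midranked ties. The
#' operating threshold maximises Youden's J = sensitivity + specificity - 1
#' over the observed score cuts (classify positive when score >= t); ties
#' in J resolve toward higher sensitivity (the lower threshold).
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels logical (or 0/1) vector, TRUE = positive.
#' @return list(auc, threshold, sensitivity, specificity, J).
#' @export
rocAucYouden <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  cuts <- sort(unique(scores))
  best <- list(J = -Inf)
  for (t in rev(cuts)) {                     # descending: later = higher sens
    sens <- mean(scores[labels] >= t)
    spec <- mean(scores[!labels] < t)
    J <- sens + spec - 1
    if (J >= best$J + 1e-12 ||
        (abs(J - best$J) < 1e-12 && sens > best$sensitivity)) {
      best <- list(J = J, threshold = t, sensitivity = sens,
                   specificity = spec)
    }
  }
  list(auc = auc, threshold = best$threshold,
       sensitivity = best$sensitivity, specificity = best$specificity,
       J = best$J)
}

#' Compose the two-stage cascade decision
#'
#' Stage 1 screens HC vs dementia; stage 2 assigns the subtype. A stage-1
#' "HC" call is final (stage 2 ignored); a dementia call requires the
#' stage-2 label.
#'
#' @param stage1Label "HC" or "dementia" (vectorised).
#' @param stage2Label "AD" or "FTD"; may be NA where stage 1 said HC.
#' @return 3-class label(s): HC, AD or FTD.
#' @export
cascadePredict <- function(stage1Label, stage2Label) {
  n <- max(length(stage1Label), length(stage2Label))
  stage1Label <- rep_len(stage1Label, n)
  stage2Label <- rep_len(stage2Label, n)
  out <- character(n)
  for (i in seq_len(n)) {
    if (stage1Label[i] == "HC") out[i] <- "HC"
    else {
      if (is.na(stage2Label[i]))
        stop("missing stage-2 label for a dementia call")
      out[i] <- stage2Label[i]
    }
  }
  out
}
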