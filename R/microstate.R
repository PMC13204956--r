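#' Global field power
#'
#' GFP(t) is the spatial standard deviation of the scalp potential field at
#' time t: \code{sqrt(mean((V_i(t) - mean_i V_i(t))^2))} over the N
#' electrodes. Peaks of GFP mark moments of maximal topographic
#' signal-to-noise. Invariant to adding a constant across channels, hence to
#' average re-referencing.
#'
#' @param x a numeric vector (one topography), a channels x samples matrix,
#'   or a \linkS4class{Recording}.
#' @return scalar for a vector input, else a numeric series of length T.
#' @examples
#' gfp(c(1, -1))        # 1
#' gfp(c(5, 5, 5))      # 0
#' @export
gfp <- function(x) {
  if (is(x, "Recording")) x <- eegData(x)
  if (is.matrix(x)) {
    if (nrow(x) < 2) stop("GFP needs >= 2 channels")
    cm <- colMeans(x)
    return(sqrt(colMeans(sweep(x, 2, cm)^2)))
  }
  if (length(x) < 2) stop("GFP needs >= 2 channels")
  sqrt(mean((x - mean(x))^2))
}

#' Detect strict local maxima of a GFP series
#'
#' Returns indices t with \code{g[t-1] < g[t] > g[t+1]}; endpoints are never
#' returned. May be empty (e.g. monotone series).
#'
#' @param g numeric series, length >= 3.
#' @return integer indices of the peaks.
#' @export
detectGfpPeaks <- function(g) {
  if (length(g) < 3) stop("series too short for peak detection")
  t <- 2:(length(g) - 1)
  t[g[t] > g[t - 1] & g[t] > g[t + 1]]
}

#' Spatial correlation between two topographies
#'
#' Pearson correlation across channels of the mean-removed maps; with
#' \code{polarityInvariant = TRUE} (the microstate convention: oscillation
#' phase flips the map sign) the absolute value is returned.
#'
#' @param a,b numeric topographies of equal length with nonzero variance.
#' @param polarityInvariant take the absolute value (default TRUE).
#' @return correlation in [-1, 1] (or [0, 1] when polarity-invariant).
#' @export
spatialCorr <- function(a, b, polarityInvariant = TRUE) {
  if (length(a) != length(b)) stop("topographies must have equal length")
  a <- a - mean(a); b <- b - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-variance topography")
  r <- sum(a * b) / (na * nb)
  if (polarityInvariant) abs(r) else r
}

## rows of `maps` centred to zero channel mean and unit L2 norm
normalizeMaps <- function(maps) {
  maps <- maps - rowMeans(maps)
  nrm <- sqrt(rowSums(maps^2))
  if (any(nrm == 0)) stop("zero-variance map cannot be normalized")
  maps / nrm
}

## |correlation| matrix between rows of A (n x N) and rows of B (k x N)
absCorrMatrix <- function(A, B) {
  abs(normalizeMaps(A) %*% t(normalizeMaps(B)))
}

#' Global explained variance of a template set
#'
#' GEV is the GFP-weighted squared-correlation fraction of the data variance
#' explained by the winning template at each map:
#' \code{sum((gfp_t * rho_best_t)^2) / sum(gfp_t^2)}, with rho the
#' polarity-invariant spatial correlation. Lies in [0, 1]; invariant to sign
#' flips of templates or maps.
#'
#' @param templates K x N matrix of template topographies (rows).
#' @param maps n x N matrix of observed topographies (rows).
#' @param gfpValues GFP value of each observed map (length n); computed from
#'   \code{maps} when missing.
#' @param assignment optional integer vector fixing each map's template;
#'   defaults to the best (argmax |rho|) template per map.
#' @return scalar GEV, with attribute \code{perMap}: the per-template share.
#' @export
gev <- function(templates, maps, gfpValues = NULL, assignment = NULL) {
  maps <- as.matrix(maps)
  templates <- as.matrix(templates)
  if (is.null(gfpValues)) gfpValues <- apply(maps, 1, gfp)
  denom <- sum(gfpValues^2)
  if (denom == 0) stop("all-zero GFP")
  R <- absCorrMatrix(maps, templates)
  if (is.null(assignment)) {
    best <- max.col(R, ties.method = "first")
  } else best <- assignment
  rbest <- R[cbind(seq_len(nrow(R)), best)]
  contrib <- (gfpValues * rbest)^2
  out <- sum(contrib) / denom
  per <- vapply(seq_len(nrow(templates)),
                function(k) sum(contrib[best == k]) / denom, 0)
  attr(out, "perMap") <- per
  out
}

#' Polarity-invariant modified k-means over GFP-peak topographies
#'
#' Clusters peak maps into K templates with the microstate variant of
#' k-means: assignment by maximal absolute spatial correlation, template
#' update as the dominant eigenvector of the outer-product sum of the
#' assigned maps (sign-proof, unlike a signed mean). Iterates until the
#' assignment stabilises (or GEV improves by < \code{tol}), across
#' \code{nRestarts} random initialisations (K observed maps each); the
#' restart with the highest GEV wins. Emptied clusters are re-seeded from a
#' random map.
#'
#' @param peakMaps n x N matrix, one GFP-peak topography per row (n >= K).
#' @param K number of templates (default 4).
#' @param nRestarts random restarts (default 20).
#' @param maxIter iteration cap per restart (default 100).
#' @param seed optional RNG seed for reproducible restarts.
#' @param gfpValues per-map GFP weights for the GEV criterion; computed from
#'   \code{peakMaps} when missing.
#' @param band band name recorded in the result.
#' @param channels channel names recorded in the result.
#' @param tol GEV improvement convergence threshold (default 1e-6).
#' @return a \linkS4class{TemplateSet} with provisional labels A-D in
#'   cluster order (use \code{\link{labelCanonical}} or
#'   \code{\link{alignBands}} to assign canonical classes).
#' @export
modifiedKmeans <- function(peakMaps, K = 4, nRestarts = 20, maxIter = 100,
                           seed = NULL, gfpValues = NULL, band = "broadband",
                           channels = colnames(peakMaps), tol = 1e-6) {
  peakMaps <- as.matrix(peakMaps)
  n <- nrow(peakMaps)
  if (n < K) stop("need at least K peak maps (", n, " < ", K, ")")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(gfpValues)) gfpValues <- apply(peakMaps, 1, gfp)
  X <- normalizeMaps(peakMaps)
  if (K > 1) {
    R <- abs(X %*% t(X))
    if (min(R) > 1 - 1e-9)
      warning("all peak maps identical up to sign: clustering degenerate")
  }
  domEig <- function(rowsIdx) {
    S <- crossprod(X[rowsIdx, , drop = FALSE])
    e <- eigen(S, symmetric = TRUE)
    v <- e$vectors[, 1]
    v <- v - mean(v)
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(NULL)
    v / nv
  }
  best <- NULL
  bestGev <- -Inf
  for (r in seq_len(nRestarts)) {
    tmpl <- X[sample.int(n, K), , drop = FALSE]
    assign_ <- rep(0L, n)
    lastGev <- -Inf
    for (it in seq_len(maxIter)) {
      R <- abs(X %*% t(tmpl))
      newAssign <- max.col(R, ties.method = "first")
      for (k in seq_len(K)) {
        idx <- which(newAssign == k)
        if (!length(idx)) {                 # re-seed emptied cluster
          tmpl[k, ] <- X[sample.int(n, 1), ]
          next
        }
        v <- domEig(idx)
        if (!is.null(v)) tmpl[k, ] <- v
      }
      g <- gev(tmpl, X, gfpValues = gfpValues)
      if (identical(newAssign, assign_) || (g - lastGev) < tol) {
        assign_ <- newAssign
        lastGev <- max(g, lastGev)
        break
      }
      assign_ <- newAssign
      lastGev <- g
    }
    g <- gev(tmpl, X, gfpValues = gfpValues)
    if (g > bestGev) {
      bestGev <- g
      best <- list(templates = tmpl, gev = g, perMap = attr(g, "perMap"))
    }
  }
  maps <- normalizeMaps(best$templates)
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(maps)))
  colnames(maps) <- channels
  if (K != 4) {                   # non-canonical K: plain result
    return(list(maps = maps, gevTotal = as.numeric(best$gev),
                gevPerMap = attr(best$gev, "perMap"), nPeakMaps = n))
  }
  rownames(maps) <- MS_CLASSES
  new("TemplateSet", band = band, maps = maps, labels = rownames(maps),
      gevTotal = as.numeric(best$gev), gevPerMap = attr(best$gev, "perMap"),
      nPeakMaps = n, channels = channels)
}

## permute template rows into canonical A-D order given assignment to anchors
permuteTemplates <- function(ts, assign_, anchorLabels, costTotal, costMat) {
  ord <- order(assign_)                     # row of ts matched to anchor k
  maps <- ts@maps[ord, , drop = FALSE]
  labels <- anchorLabels[assign_[ord]]
  rownames(maps) <- labels
  ts@maps <- maps
  ts@labels <- labels
  ts@gevPerMap <- ts@gevPerMap[ord]
  attr(ts, "alignmentCost") <- costTotal
  attr(ts, "costMatrix") <- costMat
  ts
}

#' Assign canonical A-D labels to broadband templates
#'
#' Matches clustered templates against the built-in canonical prototype
#' geometries (A: right-anterior/left-posterior diagonal, B: mirrored
#' diagonal, C: anterior-posterior midline, D: posterior-focal) by
#' minimum-cost bipartite assignment on cost 1 - |spatial correlation|.
#' The microstate literature never fixes how clusters receive their letters;
#' this prototype-matching rule is this package's documented convention.
#'
#' @param ts a \linkS4class{TemplateSet} (typically broadband).
#' @param prototypes 4 x N matrix of prototype maps, rows named A-D;
#'   defaults to \code{\link{makePrototypes}} on the matching montage.
#' @return the relabelled \linkS4class{TemplateSet}, rows in A-D order;
#'   attributes \code{alignmentCost} and \code{costMatrix} report the match.
#' @export
labelCanonical <- function(ts, prototypes = NULL) {
  stopifnot(is(ts, "TemplateSet"))
  if (is.null(prototypes)) {
    mon <- montage1020()
    mon <- mon[match(ts@channels, mon$channel), ]
    if (anyNA(mon$x)) stop("montage positions missing for some channels")
    prototypes <- makePrototypes(mon)
  }
  C <- absCorrMatrix(ts@maps, prototypes)   # rows: templates, cols: prototypes
  D <- 1 - C
  a <- hungarianAssign(D)
  permuteTemplates(ts, a, rownames(prototypes), attr(a, "cost"), D)
}

#' Align narrowband templates to a broadband anchor
#'
#' Computes the absolute spatial correlation matrix C between narrowband
#' templates and anchor templates, the cost matrix D = 1 - C, and solves the
#' minimum-cost one-to-one assignment with the Hungarian algorithm; the
#' narrowband rows are relabelled/reordered so classes A-D keep a consistent
#' physiological meaning across bands.
#'
#' @param narrow narrowband \linkS4class{TemplateSet}.
#' @param anchor anchor (broadband) \linkS4class{TemplateSet}, canonical
#'   labels already assigned.
#' @return aligned \linkS4class{TemplateSet} with attributes
#'   \code{alignmentCost} (total assignment cost) and \code{costMatrix}.
#' @export
alignBands <- function(narrow, anchor) {
  stopifnot(is(narrow, "TemplateSet"), is(anchor, "TemplateSet"))
  if (!identical(narrow@channels, anchor@channels))
    stop("montage mismatch between template sets")
  C <- absCorrMatrix(narrow@maps, anchor@maps)
  D <- 1 - C
  a <- hungarianAssign(D)
  permuteTemplates(narrow, a, anchor@labels, attr(a, "cost"), D)
}

#' Soft backfitting: continuous template correlation trajectories
#'
#' For every time frame x(t) of an epoch, computes the polarity-invariant
#' spatial correlation r_k(t) = |rho(x(t), m_k)| with each aligned template
#' m_k, k in A-D. No winner-takes-all discretisation is applied: the result
#' is a (4 x T) trajectory with values in [0, 1]. Zero-variance frames have
#' undefined correlation; they are emitted as 0 and flagged.
#'
#' @param epochData channels x T matrix (one epoch), average-referenced.
#' @param templates aligned \linkS4class{TemplateSet}.
#' @param subjectId,epochIndex provenance carried into the result.
#' @param polarityInvariant absolute-value mode (default TRUE). Signed mode
#'   retains the correlation sign and therefore returns a plain 4 x T matrix
#'   (with a \code{flaggedFrames} attribute) rather than a
#'   \linkS4class{SoftSequence}, whose values are [0,1] by contract.
#' @return a \linkS4class{SoftSequence} (or a matrix in signed mode).
#' @export
backfitSoft <- function(epochData, templates, subjectId = "s01",
                        epochIndex = 1L, polarityInvariant = TRUE) {
  stopifnot(is(templates, "TemplateSet"))
  x <- as.matrix(epochData)
  if (nrow(x) != length(templates@channels))
    stop("epoch channels do not match template montage")
  M <- normalizeMaps(templates@maps)        # 4 x N, rows A-D
  xc <- sweep(x, 2, colMeans(x))
  nrm <- sqrt(colSums(xc^2))
  flagged <- which(nrm == 0)
  nrm[flagged] <- 1
  R <- (M %*% xc) / rep(nrm, each = 4)
  R[, flagged] <- 0
  R[R > 1] <- 1                             # guard rounding
  R[R < -1] <- -1
  rownames(R) <- templates@labels
  if (!polarityInvariant) {
    attr(R, "flaggedFrames") <- as.integer(flagged)
    return(R)
  }
  new("SoftSequence", band = templates@band, values = abs(R),
      subjectId = subjectId, epochIndex = as.integer(epochIndex),
      flaggedFrames = as.integer(flagged))
}

#' Fuse two soft sequences into a stage input
#'
#' Stacks the first band's rows A-D over the second band's rows A-D into an
#' 8 x T matrix (row-block order fixed: rows 1-4 = first band, rows 5-8 =
#' second band). Stage 1 fuses alpha+delta, stage 2 delta+theta.
#'
#' @param first,second \linkS4class{SoftSequence}s of the same epoch of the
#'   same subject, equal T.
#' @param stage "stage1" or "stage2".
#' @param label optional class label for training.
#' @return a \linkS4class{FusedEpoch}.
#' @export
fuseBands <- function(first, second, stage = c("stage1", "stage2"),
                      label = NA_character_) {
  stage <- match.arg(stage)
  stopifnot(is(first, "SoftSequence"), is(second, "SoftSequence"))
  if (ncol(first@values) != ncol(second@values))
    stop("length mismatch between soft sequences")
  if (!identical(first@subjectId, second@subjectId) ||
      !identical(first@epochIndex, second@epochIndex))
    stop("subject/epoch mismatch between soft sequences")
  v <- rbind(first@values, second@values)
  rownames(v) <- c(paste0(first@band, ".", rownames(first@values)),
                   paste0(second@band, ".", rownames(second@values)))
  new("FusedEpoch", stage = stage, bands = c(first@band, second@band),
      values = v, label = as.character(label),
      subjectId = first@subjectId, epochIndex = first@epochIndex)
}

#' Canonical microstate statistics of a soft sequence
#'
#' Discretises a soft sequence by per-sample argmax, merges consecutive
#' equal labels into segments, and reports the classic microstate summary
#' statistics: coverage (sample share per class), mean dwell time (ms),
#' occurrence (segments per second) and the segment-level transition matrix
#' (rows normalised over observed transitions; classes with no outgoing
#' transition keep an all-zero row and are flagged).
#'
#' @param seq a \linkS4class{SoftSequence}, or a character/factor vector of
#'   per-sample labels in A-D.
#' @param rate sampling rate in Hz.
#' @return list with elements \code{coverage}, \code{meanDwellMs},
#'   \code{occurrence}, \code{transitions}, \code{emptyRows}, \code{labels}.
#' @export
microstateStats <- function(seq, rate) {
  if (is(seq, "SoftSequence")) {
    v <- seq@values
    lab <- rownames(v)[max.col(t(v), ties.method = "first")]
  } else lab <- as.character(seq)
  T_ <- length(lab)
  if (T_ < 2) stop("sequence too short")
  cls <- MS_CLASSES
  coverage <- vapply(cls, function(k) mean(lab == k), 0)
  runs <- rle(lab)
  segs <- runs$values
  lens <- runs$lengths
  durS <- T_ / rate
  occurrence <- vapply(cls, function(k) sum(segs == k) / durS, 0)
  meanDwellMs <- vapply(cls, function(k) {
    l <- lens[segs == k]
    if (!length(l)) return(NA_real_)
    mean(l) / rate * 1000
  }, 0)
  trans <- matrix(0, 4, 4, dimnames = list(cls, cls))
  if (length(segs) > 1) {
    from <- segs[-length(segs)]
    to <- segs[-1]
    for (i in seq_along(from)) trans[from[i], to[i]] <- trans[from[i], to[i]] + 1
  }
  rs <- rowSums(trans)
  emptyRows <- cls[rs == 0]
  nz <- rs > 0
  trans[nz, ] <- trans[nz, , drop = FALSE] / rs[nz]
  list(coverage = coverage, meanDwellMs = meanDwellMs,
       occurrence = occurrence, transitions = trans,
       emptyRows = emptyRows, labels = lab)
}

#' Serialize a TemplateSet to JSON
#'
#' @param ts a \linkS4class{TemplateSet}.
#' @param path output path; when NULL the JSON string is returned.
#' @export
writeTemplateSet <- function(ts, path = NULL) {
  stopifnot(is(ts, "TemplateSet"))
  obj <- list(band = ts@band, labels = ts@labels, channels = ts@channels,
              gevTotal = ts@gevTotal, gevPerMap = ts@gevPerMap,
              nPeakMaps = ts@nPeakMaps,
              maps = apply(ts@maps, 1, identity, simplify = FALSE))
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a TemplateSet from JSON written by \code{\link{writeTemplateSet}}
#' @param path JSON file path.
#' @export
readTemplateSet <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path, warn = FALSE))
  maps <- do.call(rbind, obj$maps)
  rownames(maps) <- obj$labels
  colnames(maps) <- obj$channels
  new("TemplateSet", band = obj$band, maps = maps, labels = obj$labels,
      gevTotal = obj$gevTotal, gevPerMap = obj$gevPerMap,
      nPeakMaps = obj$nPeakMaps, channels = obj$channels)
}
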