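#' @import methods
NULL

MS_CLASSES <- c("A", "B", "C", "D")
MS_GROUPS <- c("AD", "FTD", "HC", "unknown")

## Canonical frequency band grid (Hz). Broadband doubles as the template anchor.
BAND_GRID <- list(
  broadband = c(0.5, 45),
  delta     = c(0.5, 4),
  theta     = c(4, 8),
  alpha     = c(8, 13),
  beta      = c(13, 30),
  gamma     = c(30, 45)
)

#' Frequency band specification
#'
#' A named frequency band with lower and upper edges in Hz. The canonical
#' band grid covers broadband (0.5-45), delta (0.5-4), theta (4-8),
#' alpha (8-13), beta (13-30) and gamma (30-45) Hz.
#'
#' @slot name band name.
#' @slot low,high band edges in Hz.
#' @export
setClass("BandSpec",
  representation(name = "character", low = "numeric", high = "numeric"),
  validity = function(object) {
    if (length(object@low) != 1 || length(object@high) != 1)
      return("low/high must be scalars")
    if (!(object@low > 0)) return("low must be > 0")
    if (!(object@high > object@low)) return("high must exceed low")
    TRUE
  })

#' Construct a band specification
#'
#' @param name one of \code{broadband, delta, theta, alpha, beta, gamma}, or
#'   any label when \code{low}/\code{high} are given explicitly.
#' @param low,high band edges in Hz; defaulted from the canonical grid when
#'   \code{name} is one of the canonical bands.
#' @return a \linkS4class{BandSpec}.
#' @examples
#' bandSpec("alpha")
#' bandSpec("custom", 2, 6)
#' @export
bandSpec <- function(name, low = NULL, high = NULL) {
  if (is.null(low) || is.null(high)) {
    if (!name %in% names(BAND_GRID))
      stop("unknown band '", name, "'; give low/high explicitly")
    low <- BAND_GRID[[name]][1]
    high <- BAND_GRID[[name]][2]
  }
  new("BandSpec", name = name, low = low, high = high)
}

#' Multichannel EEG recording
#'
#' One subject's referenced multichannel EEG: a channels x samples matrix of
#' potentials in microvolts, with montage channel names, sampling rate and an
#' optional diagnostic group label.
#'
#' @slot subjectId subject identifier.
#' @slot group diagnostic label: AD, FTD, HC or unknown.
#' @slot channels ordered electrode names (10-20 montage by default).
#' @slot rate sampling frequency in Hz.
#' @slot data channels x samples matrix, microvolts.
#' @slot reference free-text provenance tag for the reference scheme.
#' @export
setClass("Recording",
  representation(subjectId = "character", group = "character",
                 channels = "character", rate = "numeric",
                 data = "matrix", reference = "character"),
  prototype(group = "unknown", reference = "as-recorded"),
  validity = function(object) {
    if (nrow(object@data) != length(object@channels))
      return("data row count must equal channel count")
    if (length(object@rate) != 1 || object@rate <= 0)
      return("rate must be a positive scalar")
    if (!all(is.finite(object@data)))
      return("data must be finite")
    if (anyDuplicated(object@channels))
      return("channel names must be unique")
    if (!object@group %in% MS_GROUPS)
      return("group must be one of AD, FTD, HC, unknown")
    TRUE
  })

#' Construct a Recording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param rate sampling rate in Hz.
#' @param channels electrode names; default taken from matrix rownames.
#' @param subjectId subject identifier.
#' @param group diagnostic label (AD, FTD, HC, unknown).
#' @param reference reference provenance tag.
#' @return a \linkS4class{Recording}.
#' @export
Recording <- function(data, rate, channels = rownames(data),
                      subjectId = "s01", group = "unknown",
                      reference = "as-recorded") {
  data <- as.matrix(data)
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(data)))
  rownames(data) <- channels
  new("Recording", subjectId = subjectId, group = group,
      channels = channels, rate = rate, data = data, reference = reference)
}

#' Windowed epochs of one subject's band-filtered EEG
#'
#' @slot subjectId subject identifier.
#' @slot band band name the epochs were filtered to.
#' @slot epochs list of channels x L matrices, identical shapes.
#' @slot windowS,stepS window length and step in seconds.
#' @slot channels electrode names.
#' @slot rate sampling rate in Hz.
#' @export
setClass("EpochSet",
  representation(subjectId = "character", band = "character",
                 epochs = "list", windowS = "numeric", stepS = "numeric",
                 channels = "character", rate = "numeric"),
  validity = function(object) {
    if (length(object@epochs) > 0) {
      dims <- vapply(object@epochs, dim, integer(2))
      if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
        return("all epochs must have identical shape")
      if (dims[1, 1] != length(object@channels))
        return("epoch row count must equal channel count")
    }
    TRUE
  })

#' Microstate template set for one frequency band
#'
#' Four unit-norm, channel-mean-zero template topographies with their global
#' explained variance, carrying canonical class labels A-D. Rows are kept in
#' canonical A, B, C, D order once labelled/aligned.
#'
#' @slot band band name.
#' @slot maps 4 x N matrix of template topographies (rows = classes).
#' @slot labels permutation of A, B, C, D giving each row's class.
#' @slot gevTotal total global explained variance of the clustering.
#' @slot gevPerMap per-template GEV contribution.
#' @slot nPeakMaps number of GFP-peak topographies clustered.
#' @slot channels montage channel names.
#' @export
setClass("TemplateSet",
  representation(band = "character", maps = "matrix", labels = "character",
                 gevTotal = "numeric", gevPerMap = "numeric",
                 nPeakMaps = "numeric", channels = "character"),
  validity = function(object) {
    if (nrow(object@maps) != 4) return("maps must have 4 rows")
    if (!setequal(object@labels, MS_CLASSES))
      return("labels must be a bijection onto {A,B,C,D}")
    nm <- sqrt(rowSums(object@maps^2))
    if (any(abs(nm - 1) > 1e-6)) return("template maps must be unit norm")
    if (any(abs(rowMeans(object@maps)) > 1e-6))
      return("template maps must have zero channel mean")
    if (any(object@gevTotal < -1e-12 | object@gevTotal > 1 + 1e-12))
      return("gevTotal must lie in [0,1]")
    TRUE
  })

#' Continuous soft-assignment microstate sequence for one epoch
#'
#' Polarity-invariant spatial correlation trajectories between each time
#' frame of an epoch and the four aligned templates: a 4 x T matrix with
#' values in [0, 1], rows in class order A-D.
#'
#' @slot band band name.
#' @slot values 4 x T matrix of correlations in [0,1].
#' @slot subjectId subject identifier.
#' @slot epochIndex index of the epoch within its subject.
#' @slot flaggedFrames indices of zero-variance frames emitted as 0.
#' @export
setClass("SoftSequence",
  representation(band = "character", values = "matrix",
                 subjectId = "character", epochIndex = "integer",
                 flaggedFrames = "integer"),
  validity = function(object) {
    if (nrow(object@values) != 4) return("values must have 4 rows")
    if (any(object@values < -1e-9 | object@values > 1 + 1e-9))
      return("soft values must lie in [0,1]")
    TRUE
  })

#' Two-band fused classifier input for one epoch
#'
#' Stacks two bands' soft sequences into an 8 x T matrix: rows 1-4 carry the
#' first band's classes A-D, rows 5-8 the second band's, fixed ordering.
#'
#' @slot stage "stage1" (alpha+delta) or "stage2" (delta+theta).
#' @slot bands the two band names in row-block order.
#' @slot values 8 x T matrix in [0,1].
#' @slot label class label attached for training (may be NA).
#' @slot subjectId subject identifier.
#' @slot epochIndex epoch index within subject.
#' @export
setClass("FusedEpoch",
  representation(stage = "character", bands = "character", values = "matrix",
                 label = "character", subjectId = "character",
                 epochIndex = "integer"),
  validity = function(object) {
    if (nrow(object@values) != 8) return("values must have 8 rows")
    if (length(object@bands) != 2) return("exactly two bands")
    if (any(object@values < -1e-9 | object@values > 1 + 1e-9))
      return("fused values must lie in [0,1]")
    if (!object@stage %in% c("stage1", "stage2"))
      return("stage must be stage1 or stage2")
    TRUE
  })

## ---- generics & accessors -------------------------------------------------

#' @rdname Recording-class
#' @param object,x an object.
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))
#' @export
setGeneric("epochs", function(x) standardGeneric("epochs"))
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))
#' @export
setGeneric("templateMaps", function(x) standardGeneric("templateMaps"))
#' @export
setGeneric("templateLabels", function(x) standardGeneric("templateLabels"))
#' @export
setGeneric("gevTotal", function(x) standardGeneric("gevTotal"))
#' @export
setGeneric("softValues", function(x) standardGeneric("softValues"))
#' @export
setGeneric("fusedValues", function(x) standardGeneric("fusedValues"))
#' @export
setGeneric("bandName", function(x) standardGeneric("bandName"))

#' @export
setMethod("subjectId", "Recording", function(x) x@subjectId)
#' @export
setMethod("subjectId", "EpochSet", function(x) x@subjectId)
#' @export
setMethod("subjectId", "SoftSequence", function(x) x@subjectId)
#' @export
setMethod("subjectId", "FusedEpoch", function(x) x@subjectId)
#' @export
setMethod("channelNames", "Recording", function(x) x@channels)
#' @export
setMethod("channelNames", "EpochSet", function(x) x@channels)
#' @export
setMethod("channelNames", "TemplateSet", function(x) x@channels)
#' @export
setMethod("samplingRate", "Recording", function(x) x@rate)
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@rate)
#' @export
setMethod("eegData", "Recording", function(x) x@data)
#' @export
setMethod("groupLabel", "Recording", function(x) x@group)
#' @export
setMethod("epochs", "EpochSet", function(x) x@epochs)
#' @export
setMethod("nEpochs", "EpochSet", function(x) length(x@epochs))
#' @export
setMethod("templateMaps", "TemplateSet", function(x) x@maps)
#' @export
setMethod("templateLabels", "TemplateSet", function(x) x@labels)
#' @export
setMethod("gevTotal", "TemplateSet", function(x) x@gevTotal)
#' @export
setMethod("softValues", "SoftSequence", function(x) x@values)
#' @export
setMethod("fusedValues", "FusedEpoch", function(x) x@values)
#' @export
setMethod("bandName", "BandSpec", function(x) x@name)
#' @export
setMethod("bandName", "EpochSet", function(x) x@band)
#' @export
setMethod("bandName", "TemplateSet", function(x) x@band)
#' @export
setMethod("bandName", "SoftSequence", function(x) x@band)

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording '%s' [%s]: %d channels x %d samples @ %g Hz (%s)\n",
              object@subjectId, object@group, nrow(object@data),
              ncol(object@data), object@rate, object@reference))
})
setMethod("show", "BandSpec", function(object) {
  cat(sprintf("BandSpec %s: %g-%g Hz\n", object@name, object@low, object@high))
})
setMethod("show", "EpochSet", function(object) {
  L <- if (length(object@epochs)) ncol(object@epochs[[1]]) else 0
  cat(sprintf("EpochSet '%s' band=%s: %d epochs of %d ch x %d samples (%gs/%gs)\n",
              object@subjectId, object@band, length(object@epochs),
              length(object@channels), L, object@windowS, object@stepS))
})
setMethod("show", "TemplateSet", function(object) {
  cat(sprintf("TemplateSet band=%s: 4 x %d maps [%s], GEV=%.3f (n=%d peak maps)\n",
              object@band, ncol(object@maps),
              paste(object@labels, collapse = ","),
              object@gevTotal, as.integer(object@nPeakMaps)))
})
setMethod("show", "SoftSequence", function(object) {
  cat(sprintf("SoftSequence '%s' epoch %d band=%s: 4 x %d, %d flagged frames\n",
              object@subjectId, object@epochIndex, object@band,
              ncol(object@values), length(object@flaggedFrames)))
})
setMethod("show", "FusedEpoch", function(object) {
  cat(sprintf("FusedEpoch '%s' epoch %d %s [%s+%s]: 8 x %d, label=%s\n",
              object@subjectId, object@epochIndex, object@stage,
              object@bands[1], object@bands[2], ncol(object@values),
              object@label))
})
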