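#' Re-reference a recording to the common average
#'
#' Subtracts the instantaneous mean across channels from every sample, so the
#' spatial mean is zero at every time point. Average reference is assumed by
#' topographic clustering and spatial correlation, and leaves global field
#' power unchanged (GFP already subtracts the spatial mean). Idempotent.
#'
#' @param rec a \linkS4class{Recording} with at least 2 channels.
#' @return the re-referenced \linkS4class{Recording}, reference tag "average".
#' @export
rereferenceAverage <- function(rec) {
  stopifnot(is(rec, "Recording"))
  x <- eegData(rec)
  if (nrow(x) < 2) stop("average reference needs >= 2 channels")
  x <- sweep(x, 2, colMeans(x))
  rec@data <- x
  rec@reference <- "average"
  rec
}

#' Zero-phase Butterworth band-pass filter
#'
#' Order-4 Butterworth band-pass applied forward-backward
#' (\code{signal::filtfilt}), i.e. zero phase distortion and an effective
#' magnitude response squared. Passband gain is ~1 and stopband attenuation
#' strong across the canonical EEG band grid at 256 Hz.
#'
#' @param rec a \linkS4class{Recording}.
#' @param band a \linkS4class{BandSpec} or band name.
#' @param order filter order (default 4).
#' @return filtered \linkS4class{Recording}.
#' @export
bandpass <- function(rec, band, order = 4) {
  stopifnot(is(rec, "Recording"))
  if (is.character(band)) band <- bandSpec(band)
  nyq <- samplingRate(rec) / 2
  if (band@high >= nyq)
    stop(sprintf("band edge %.3g Hz exceeds Nyquist %.3g Hz", band@high, nyq))
  bf <- signal::butter(order, c(band@low, band@high) / nyq, type = "pass")
  x <- eegData(rec)
  y <- t(apply(x, 1, function(ch) signal::filtfilt(bf, ch)))
  rownames(y) <- rownames(x)
  rec@data <- y
  rec@reference <- paste0(rec@reference, "+bp[", band@name, "]")
  rec
}

#' Resample a recording
#'
#' Polyphase resampling with anti-alias low-pass filtering
#' (\code{signal::resample}). The output length is
#' \code{round(L * targetRate / rate)}; pure tones keep their spectral peak
#' within frequency resolution. Upsampling is permitted but noted.
#'
#' @param rec a \linkS4class{Recording}.
#' @param targetRate new sampling rate in Hz (positive).
#' @return resampled \linkS4class{Recording}.
#' @export
resampleRecording <- function(rec, targetRate) {
  stopifnot(is(rec, "Recording"))
  if (!is.numeric(targetRate) || length(targetRate) != 1 || targetRate <= 0)
    stop("targetRate must be a positive scalar")
  rate <- samplingRate(rec)
  if (targetRate == rate) return(rec)
  if (targetRate > rate)
    message("upsampling ", rate, " -> ", targetRate, " Hz")
  frac <- ratApprox(targetRate / rate)
  x <- eegData(rec)
  nOut <- round(ncol(x) * targetRate / rate)
  y <- t(apply(x, 1, function(ch) {
    z <- signal::resample(ch, frac[1], frac[2])
    if (length(z) >= nOut) z[seq_len(nOut)] else c(z, rep(z[length(z)], nOut - length(z)))
  }))
  rownames(y) <- rownames(x)
  rec@data <- y
  rec@rate <- targetRate
  rec
}

## small-denominator rational approximation of a rate ratio
ratApprox <- function(r, maxDen = 10000) {
  for (q in seq_len(maxDen)) {
    p <- r * q
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  stop("cannot express rate ratio ", r, " as a small fraction")
}

#' Number of sliding-window epochs
#'
#' Boundary convention: window starts k*S (0-based) with k*S + W strictly
#' less than L, i.e. the window ending exactly at the recording end is
#' excluded: \code{floor((L - W - 1)/S) + 1} for L > W, else 0. At the study
#' defaults (300 s at 256 Hz, 10 s windows, 5 s steps) this yields 58 epochs
#' per subject.
#'
#' @param nSamples total samples L.
#' @param windowSamples window length W in samples.
#' @param stepSamples step S in samples.
#' @return integer epoch count.
#' @export
epochCount <- function(nSamples, windowSamples, stepSamples) {
  if (nSamples <= windowSamples) return(0L)
  as.integer((nSamples - windowSamples - 1) %/% stepSamples + 1L)
}

#' Cut a recording into overlapping epochs
#'
#' Sliding windows of \code{windowS} seconds advancing by \code{stepS}
#' seconds (50\% overlap at the defaults). Epoch k covers the half-open
#' 0-based sample interval [k*S, k*S + W); see \code{\link{epochCount}} for
#' the boundary convention. A recording shorter than one window yields an
#' empty set with a warning.
#'
#' @param rec a \linkS4class{Recording}.
#' @param windowS window length in seconds (default 10).
#' @param stepS step in seconds (default 5).
#' @return an \linkS4class{EpochSet}.
#' @export
epochRecording <- function(rec, windowS = 10, stepS = 5) {
  stopifnot(is(rec, "Recording"))
  if (windowS <= 0 || stepS <= 0) stop("window and step must be positive")
  rate <- samplingRate(rec)
  W <- round(windowS * rate)
  S <- round(stepS * rate)
  L <- ncol(eegData(rec))
  n <- epochCount(L, W, S)
  if (n == 0L)
    warning("recording shorter than one window: empty epoch set")
  x <- eegData(rec)
  eps <- lapply(seq_len(n), function(k) x[, ((k - 1) * S + 1):((k - 1) * S + W), drop = FALSE])
  new("EpochSet", subjectId = subjectId(rec), band = "broadband",
      epochs = eps, windowS = windowS, stepS = stepS,
      channels = channelNames(rec), rate = rate)
}
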