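## Minimal BrainVision (vhdr/vmrk/eeg) support: INI-style text header, binary
## multiplexed data as IEEE_FLOAT_32 or INT_16 (with per-channel resolution).

#' Write a Recording as a BrainVision file triplet
#'
#' @param rec a \linkS4class{Recording}.
#' @param basePath path without extension; writes .vhdr, .vmrk and .eeg.
#' @param binaryFormat "IEEE_FLOAT_32" (default) or "INT_16".
#' @return the .vhdr path, invisibly.
#' @export
writeBrainVision <- function(rec, basePath, binaryFormat = "IEEE_FLOAT_32") {
  stopifnot(is(rec, "Recording"),
            binaryFormat %in% c("IEEE_FLOAT_32", "INT_16"))
  vhdr <- paste0(basePath, ".vhdr")
  vmrk <- paste0(basePath, ".vmrk")
  eeg <- paste0(basePath, ".eeg")
  x <- eegData(rec)
  ns <- nrow(x)
  res <- rep(1, ns)
  if (binaryFormat == "INT_16") {
    res <- pmax(apply(abs(x), 1, max), 1e-12) / 32000
  }
  chlines <- sprintf("Ch%d=%s,,%.10g,µV", seq_len(ns),
                     channelNames(rec), res)
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    ";Written by mscascade",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s", basename(eeg)),
    sprintf("MarkerFile=%s", basename(vmrk)),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", ns),
    sprintf("SamplingInterval=%.10g", 1e6 / samplingRate(rec)),
    "",
    "[Binary Infos]",
    sprintf("BinaryFormat=%s", binaryFormat),
    "",
    "[Channel Infos]",
    chlines), vhdr, useBytes = TRUE)
  writeLines(c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    sprintf("DataFile=%s", basename(eeg)),
    "",
    "[Marker Infos]",
    sprintf("Mk1=New Segment,,1,1,0,00000000000000000000")), vmrk)
  con <- file(eeg, "wb")
  on.exit(close(con))
  if (binaryFormat == "IEEE_FLOAT_32") {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  } else {
    dig <- round(x / res)
    dig[dig > 32767] <- 32767; dig[dig < -32768] <- -32768
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(vhdr)
}

parseVhdr <- function(vhdr) {
  lines <- readLines(vhdr, warn = FALSE, encoding = "UTF-8")
  kv <- function(key) {
    hit <- grep(sprintf("^%s=", key), lines, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(sprintf("^%s=", key), "", hit[1])
  }
  chlines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  parts <- strsplit(sub("^Ch[0-9]+=", "", chlines), ",")
  list(
    dataFile = kv("DataFile"),
    format = kv("DataFormat"),
    orientation = kv("DataOrientation"),
    binaryFormat = kv("BinaryFormat"),
    nChannels = as.integer(kv("NumberOfChannels")),
    samplingInterval = as.numeric(kv("SamplingInterval")),
    channels = vapply(parts, `[`, "", 1),
    resolution = vapply(parts, function(p) {
      r <- suppressWarnings(as.numeric(p[3]))
      if (is.na(r)) 1 else r
    }, 0))
}

#' Read a BrainVision recording
#'
#' Supports binary multiplexed IEEE_FLOAT_32 and INT_16 data.
#'
#' @param vhdrPath path to the .vhdr header.
#' @param subjectId optional subject id (defaults to the file stem).
#' @param group optional diagnostic label.
#' @return a \linkS4class{Recording}.
#' @export
readBrainVision <- function(vhdrPath, subjectId = NULL, group = "unknown") {
  if (!file.exists(vhdrPath)) stop("file not found: ", vhdrPath)
  h <- parseVhdr(vhdrPath)
  if (is.na(h$format) || h$format != "BINARY")
    stop("unsupported DataFormat: ", h$format)
  if (h$orientation != "MULTIPLEXED")
    stop("unsupported DataOrientation: ", h$orientation)
  if (is.na(h$nChannels) || h$nChannels < 2)
    stop("header must declare >= 2 channels")
  if (length(h$channels) != h$nChannels)
    stop("channel/sample mismatch: ", length(h$channels),
         " channel entries for NumberOfChannels=", h$nChannels)
  eeg <- file.path(dirname(vhdrPath), h$dataFile)
  if (!file.exists(eeg)) stop("data file not found: ", eeg)
  sz <- file.info(eeg)$size
  con <- file(eeg, "rb")
  on.exit(close(con))
  if (h$binaryFormat == "IEEE_FLOAT_32") {
    n <- sz / 4
    raw <- readBin(con, numeric(), n = n, size = 4, endian = "little")
  } else if (h$binaryFormat == "INT_16") {
    n <- sz / 2
    raw <- readBin(con, integer(), n = n, size = 2, endian = "little")
  } else stop("unsupported BinaryFormat: ", h$binaryFormat)
  if (n %% h$nChannels != 0)
    stop("channel/sample mismatch: data length not divisible by channel count")
  x <- matrix(raw, nrow = h$nChannels)       # multiplexed: channel fastest
  if (h$binaryFormat == "INT_16") x <- x * h$resolution
  rate <- 1e6 / h$samplingInterval
  if (is.null(subjectId))
    subjectId <- sub("\\.vhdr$", "", basename(vhdrPath))
  Recording(x, rate = rate, channels = h$channels, subjectId = subjectId,
            group = group, reference = "as-recorded")
}
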