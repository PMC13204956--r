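## Minimal European Data Format (EDF) support: fixed 256-byte global header,
## 256 bytes per signal, then data records of 16-bit little-endian integers
## scaled channel-wise between physical and digital extrema.

edfPad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

edfNum <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7, width = 0)
  if (nchar(s) > width) s <- substr(formatC(x, format = "f", digits = width), 1, width)
  edfPad(s, width)
}

#' Write a Recording to an EDF file
#'
#' Writes 16-bit EDF with one-second data records. Samples are scaled per
#' channel between the channel's physical extrema and the full digital range,
#' so the round trip is exact up to ~1/65535 of the channel range. A trailing
#' partial second is zero-padded into the final record (a note attribute marks
#' the true length on read via the number of records only).
#'
#' @param rec a \linkS4class{Recording}; rate must be a positive integer.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeEDF <- function(rec, path) {
  stopifnot(is(rec, "Recording"))
  rate <- samplingRate(rec)
  if (rate != round(rate)) stop("EDF writer requires an integer sampling rate")
  x <- eegData(rec)
  ns <- nrow(x)
  L <- ncol(x)
  nrec <- ceiling(L / rate)
  if (nrec * rate > L) {
    x <- cbind(x, matrix(0, ns, nrec * rate - L))
  }
  pmin_ <- apply(x, 1, min)
  pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edfPad("0", 8),
    edfPad(subjectId(rec), 80),
    edfPad(paste0("Startdate X group=", groupLabel(rec)), 80),
    edfPad("01.01.00", 8), edfPad("00.00.00", 8),
    edfPad(256 * (1 + ns), 8),
    edfPad("", 44),
    edfPad(nrec, 8),
    edfPad(1, 8),
    edfPad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, edfPad, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  field(channelNames(rec), 16)
  field(rep("", ns), 80)                     # transducer
  field(rep("uV", ns), 8)                    # physical dimension
  field(vapply(pmin_, edfNum, "", width = 8), 8)
  field(vapply(pmax_, edfNum, "", width = 8), 8)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80)                     # prefiltering
  field(rep(rate, ns), 8)                    # samples per record
  field(rep("", ns), 32)

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  dig <- round((x - pmin_) * scale + dmin)
  dig[dig < dmin] <- dmin
  dig[dig > dmax] <- dmax
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * rate + 1):(r * rate)
    block <- t(dig[, idx, drop = FALSE])     # samples x channels -> by signal
    writeBin(as.integer(block), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a Recording
#'
#' Minimal reader for 16-bit continuous EDF: all signals must share the
#' record sample count (equal sampling rates). Annotation channels are not
#' supported and raise an error identifying the offending channel.
#'
#' @param path EDF file path.
#' @param subjectId optional subject id; defaults to the patient field.
#' @param group optional diagnostic label; parsed from the recording field
#'   when it carries a \code{group=} tag, else "unknown".
#' @return a \linkS4class{Recording}.
#' @export
readEDF <- function(path, subjectId = NULL, group = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  version <- rd(8)
  patient <- rd(80)
  recfield <- rd(80)
  rd(8); rd(8)                               # date, time
  hbytes <- as.numeric(rd(8))
  rd(44)
  nrec <- as.numeric(rd(8))
  recdur <- as.numeric(rd(8))
  ns <- as.numeric(rd(4))
  if (is.na(ns) || ns < 2) stop("EDF must declare >= 2 signals")
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16)
  rdv(80)
  rdv(8)
  pmin_ <- as.numeric(rdv(8))
  pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8))
  dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.numeric(rdv(8))
  rdv(32)
  if (grepl("Annotation", paste(labels, collapse = " ")))
    stop("annotation channels unsupported: ",
         paste(labels[grepl("Annotation", labels)], collapse = ", "))
  if (length(unique(spr)) != 1)
    stop("channel/sample mismatch: signals have differing samples per record")
  seek(con, hbytes)
  total <- nrec * ns * spr[1]
  raw16 <- readBin(con, integer(), n = total, size = 2, endian = "little")
  if (length(raw16) < total) stop("truncated EDF data section")
  ## records: [rec][signal][sample]
  arr <- array(raw16, dim = c(spr[1], ns, nrec))
  dig <- matrix(aperm(arr, c(2, 1, 3)), nrow = ns)    # channels x samples
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  phys <- (dig - dmin) * scale + pmin_
  rate <- spr[1] / recdur
  grp <- "unknown"
  if (!is.null(group)) grp <- group
  else if (grepl("group=", recfield))
    grp <- sub(".*group=([A-Za-z]+).*", "\\1", recfield)
  if (!grp %in% MS_GROUPS) grp <- "unknown"
  Recording(phys, rate = rate, channels = labels,
            subjectId = if (is.null(subjectId)) patient else subjectId,
            group = grp, reference = "as-recorded")
}
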