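#' Read an EEG recording from EDF, BrainVision or a BIDS-like directory
#'
#' Dispatches on \code{format}: "edf" and "brainvision" read single files;
#' "bids_dir" expects a subject directory laid out as
#' \code{sub-XXX/eeg/sub-XXX_*_eeg.(edf|vhdr)} and reads the first EEG file
#' found. Group labels A/AD, F/FTD, C/HC are recognised.
#'
#' @param path file (or subject directory for "bids_dir").
#' @param format one of "edf", "brainvision", "bids_dir"; guessed from the
#'   file extension when missing.
#' @param ... passed to the underlying reader.
#' @return a \linkS4class{Recording}.
#' @export
readRecording <- function(path, format = c("edf", "brainvision", "bids_dir"),
                          ...) {
  if (missing(format)) {
    format <- if (dir.exists(path)) "bids_dir"
              else if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else if (grepl("\\.vhdr$", path, ignore.case = TRUE)) "brainvision"
              else stop("cannot guess format of ", path)
  }
  format <- match.arg(format)
  switch(format,
    edf = readEDF(path, ...),
    brainvision = readBrainVision(path, ...),
    bids_dir = {
      if (!dir.exists(path)) stop("directory not found: ", path)
      eegdir <- file.path(path, "eeg")
      if (!dir.exists(eegdir)) eegdir <- path
      files <- list.files(eegdir, pattern = "_eeg\\.(edf|vhdr)$",
                          full.names = TRUE, ignore.case = TRUE)
      if (!length(files)) stop("no EEG file under ", eegdir)
      sid <- sub("_.*$", "", basename(files[1]))
      readRecording(files[1], subjectId = sid, ...)
    })
}

normalizeGroup <- function(g) {
  g <- toupper(trimws(g))
  map <- c(A = "AD", AD = "AD", F = "FTD", FTD = "FTD", C = "HC", HC = "HC")
  out <- unname(map[g])
  out[is.na(out)] <- "unknown"
  out
}

#' Read a BIDS-like cohort directory
#'
#' Reads every \code{sub-*} subject under \code{root}; diagnostic labels are
#' taken from \code{participants.tsv} (columns \code{participant_id} and
#' \code{Group}/\code{group}) when present.
#'
#' @param root cohort root directory.
#' @return list of \linkS4class{Recording}.
#' @export
readCohort <- function(root) {
  subs <- list.dirs(root, recursive = FALSE)
  subs <- subs[grepl("^sub-", basename(subs))]
  if (!length(subs)) stop("no sub-* directories under ", root)
  groups <- NULL
  ptsv <- file.path(root, "participants.tsv")
  if (file.exists(ptsv)) {
    pt <- utils::read.delim(ptsv, stringsAsFactors = FALSE)
    gcol <- intersect(c("Group", "group"), names(pt))[1]
    if (!is.na(gcol))
      groups <- stats::setNames(normalizeGroup(pt[[gcol]]), pt$participant_id)
  }
  lapply(subs, function(s) {
    rec <- readRecording(s, format = "bids_dir")
    sid <- basename(s)
    if (!is.null(groups) && sid %in% names(groups))
      rec@group <- unname(groups[sid])
    rec@subjectId <- sid
    rec
  })
}
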