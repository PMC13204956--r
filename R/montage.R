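#' Standard 19-channel 10-20 montage
#'
#' Returns the bundled channel-location table for the 19-electrode
#' international 10-20 montage: electrode name plus 2D projected coordinates
#' (x: left negative / right positive; y: posterior negative / anterior
#' positive; head circumference at radius 1, nose up).
#'
#' @return data.frame with columns \code{channel}, \code{x}, \code{y}.
#' @examples
#' head(montage1020())
#' @export
montage1020 <- function() {
  path <- system.file("extdata", "montage_1020.tsv", package = "mscascade")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
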