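## Base-graphics topographic displays. Electrode values are shown as
## coloured discs at their 2D projected positions inside a head outline;
## no spatial interpolation (19 electrodes barely support it).

topoColors <- function(v, n = 64) {
  pal <- grDevices::hcl.colors(n, "Blue-Red 3")
  lim <- max(abs(v), 1e-12)
  pal[pmin(n, pmax(1, round((v / lim + 1) / 2 * (n - 1)) + 1))]
}

drawTopo <- function(v, montage, main = "") {
  plot(NULL, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.45), asp = 1,
       axes = FALSE, xlab = "", ylab = "", main = main)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(1.1 * cos(th), 1.1 * sin(th))
  graphics::lines(c(-0.12, 0, 0.12), c(1.09, 1.28, 1.09))   # nose
  graphics::points(montage$x, montage$y, pch = 21, cex = 2.6,
                   bg = topoColors(v), col = "grey30")
  graphics::text(montage$x, montage$y - 0.14, montage$channel, cex = 0.45)
}

#' Plot the four maps of a template set
#'
#' One head per class A-D, electrode discs coloured by potential (blue
#' negative, red positive, symmetric scale per map).
#'
#' @param ts a \linkS4class{TemplateSet}.
#' @param montage channel-location table; default the built-in 10-20 table.
#' @return invisibly, \code{ts}.
#' @export
plotTemplateSet <- function(ts, montage = montage1020()) {
  stopifnot(is(ts, "TemplateSet"))
  montage <- montage[match(ts@channels, montage$channel), ]
  op <- graphics::par(mfrow = c(1, 4), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  for (k in seq_len(4)) {
    drawTopo(ts@maps[k, ], montage,
             main = sprintf("%s (%s)", ts@labels[k], ts@band))
  }
  invisible(ts)
}

#' Overlay temporal attention on a fused epoch heatmap
#'
#' Bottom: the 8 x T fused soft-assignment matrix as a heatmap (rows 1-4 =
#' first band A-D, rows 5-8 = second band A-D). Top: the upsampled
#' head-averaged attention distribution across the same time axis.
#'
#' @param att an \code{AttentionMap} from \code{\link{extractAttention}}.
#' @param fused the matching \linkS4class{FusedEpoch} (or 8 x T matrix).
#' @param epoch which epoch row of \code{att} to draw (default 1).
#' @param rate sampling rate for the time axis, Hz.
#' @return invisibly, the attention vector drawn.
#' @export
plotAttentionOverlay <- function(att, fused, epoch = 1, rate = 256) {
  v <- if (is(fused, "FusedEpoch")) fusedValues(fused) else as.matrix(fused)
  a <- att$upsampled[epoch, ]
  T_ <- ncol(v)
  tt <- (seq_len(T_) - 1) / rate
  op <- graphics::par(mfrow = c(2, 1), mar = c(1, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(tt, a, type = "l", col = "firebrick", lwd = 1.5, xlab = "",
       ylab = "attention", main = "temporal attention", axes = FALSE)
  graphics::axis(2)
  graphics::par(mar = c(4, 4, 1, 1))
  graphics::image(tt, 1:8, t(v[8:1, , drop = FALSE]), zlim = c(0, 1),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "time (s)", ylab = "fused row", axes = FALSE)
  graphics::axis(1)
  graphics::axis(2, at = 1:8, labels = rev(rownames(v)), las = 1,
                 cex.axis = 0.6)
  invisible(a)
}
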