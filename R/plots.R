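## Base-graphics plots mirroring the figures the analyses feed:
## strength scatter with absent peaks pinned to an axis, and smoothed
## signal around a locus.

#' Scatter plot of matched peak strengths
#'
#' Each point is a merged region with a peak in at least one condition;
#' regions absent from one condition sit at 0 on that axis. The
#' percentage of regions stronger in condition B is printed in the
#' bottom-right corner.
#'
#' @param matches Output of [match_conditions()].
#' @param xlab,ylab Axis labels.
#' @param ... Passed to [graphics::plot()].
#' @return `matches`, invisibly.
#' @export
plot_strength_scatter <- function(matches, xlab = "strength (A)",
                                  ylab = "strength (B)", ...) {
  lim <- c(0, max(matches$strength_a, matches$strength_b, 1))
  graphics::plot(matches$strength_a, matches$strength_b,
                 xlim = lim, ylim = lim, xlab = xlab, ylab = ylab,
                 pch = 16, cex = 0.5,
                 col = grDevices::adjustcolor("black", 0.4), ...)
  graphics::abline(0, 1, col = "grey60", lty = 2)
  graphics::text(lim[2], 0.02 * lim[2],
                 sprintf("%.0f%%", 100 * fraction_stronger(matches)),
                 adj = c(1, 0))
  invisible(matches)
}

#' Plot one or more signal tracks over a region
#'
#' @param tracks A [signal_track()] or list of them (named for the
#'   legend).
#' @param highlight Optional `GRanges` drawn as shaded boxes (e.g. the
#'   gene body).
#' @param ylab Axis label.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `tracks`.
#' @export
plot_signal_tracks <- function(tracks, highlight = NULL,
                               ylab = "smoothed log2(IP/input)", ...) {
  if (inherits(tracks, "signal_track")) tracks <- list(signal = tracks)
  xs <- lapply(tracks, function(t) seq_along(t$values) + t$start - 1L)
  ylim <- range(unlist(lapply(tracks, `[[`, "values")))
  graphics::plot(NA, xlim = range(unlist(xs)), ylim = ylim,
                 xlab = paste0("position on ", tracks[[1]]$chrom),
                 ylab = ylab, ...)
  if (!is.null(highlight)) {
    for (i in seq_along(highlight))
      graphics::rect(GenomicRanges::start(highlight)[i], ylim[1],
                     GenomicRanges::end(highlight)[i], ylim[2],
                     col = grDevices::adjustcolor("grey", 0.4),
                     border = NA)
  }
  cols <- seq_along(tracks)
  for (i in seq_along(tracks))
    graphics::lines(xs[[i]], tracks[[i]]$values, col = cols[i])
  if (length(tracks) > 1)
    graphics::legend("topright", names(tracks), col = cols, lty = 1,
                     bty = "n")
  invisible(tracks)
}
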