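## Region-level signal tracks: per-base log2(IP/input) and Hanning
## smoothing, as used for plotting occupancy around individual genes.

#' Construct a signal track
#'
#' @param chrom Chromosome name.
#' @param start 1-based genomic position of the first value.
#' @param values Numeric vector, one value per base.
#' @return List of class `"signal_track"`.
#' @export
signal_track <- function(chrom, start, values) {
  stopifnot(length(values) > 0, all(is.finite(values)), start >= 1)
  structure(list(chrom = as.character(chrom), start = as.integer(start),
                 values = as.numeric(values)),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track %s:%d-%d (%d bp), range [%.3g, %.3g]\n",
              x$chrom, x$start, x$start + length(x$values) - 1L,
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Per-base log2 IP/input ratio
#'
#' `value_i = log2((ip_i + pseudocount) / (input_i + pseudocount))`.
#' The shared pseudocount keeps zero/zero positions at exactly 0.
#'
#' @param ip_counts,input_counts Equal-length nonnegative count vectors.
#' @param pseudocount Positive value added to both channels (default 1).
#' @param chrom,start Genomic anchoring of the track.
#' @return A [signal_track()].
#' @export
log2_ratio <- function(ip_counts, input_counts, pseudocount = 1,
                       chrom = "chr", start = 1) {
  if (length(ip_counts) != length(input_counts))
    stop("ip and input tracks differ in length (", length(ip_counts),
         " vs ", length(input_counts), ")")
  stopifnot(pseudocount > 0)
  signal_track(chrom, start,
               log2((ip_counts + pseudocount) /
                      (input_counts + pseudocount)))
}

## Hanning kernel of odd length m+1 over k = 0..m:
## w_k = 0.5 * (1 - cos(2*pi*k / m)); endpoints are 0.
.hanning_weights <- function(window_bp) {
  m <- as.integer(window_bp)
  if (m %% 2L == 1L) m <- m + 1L  # force odd kernel length m+1
  k <- 0:m
  0.5 * (1 - cos(2 * pi * k / m))
}

#' Hanning-window smoothing of a signal track
#'
#' Convolution with a Hanning window of length `window_bp + 1` (forced
#' odd so the output stays phase-aligned with the input), weights
#' normalized to sum 1. Near the track ends the truncated kernel is
#' renormalized, which avoids spurious edge dips; a constant track is
#' therefore reproduced exactly, including at the edges.
#'
#' @param track A [signal_track()].
#' @param window_bp Window length in bp (>= 3); 1000 gives the classic
#'   1 kb smoothing of gene-level occupancy plots.
#' @return Smoothed [signal_track()], same anchoring and length.
#' @export
hanning_smooth <- function(track, window_bp = 1000) {
  stopifnot(inherits(track, "signal_track"), window_bp >= 3)
  x <- track$values
  if (length(x) < 3L) stop("track shorter than 3 bases")
  w <- .hanning_weights(window_bp)
  half <- (length(w) - 1L) %/% 2L
  n <- length(x)
  num <- stats::convolve(x, w, type = "open")
  den <- stats::convolve(rep(1, n), w, type = "open")
  idx <- (half + 1L):(half + n)
  signal_track(track$chrom, track$start, num[idx] / den[idx])
}

#' Extract a centered slice of a track
#'
#' @param track A [signal_track()].
#' @param center Genomic center position (1-based).
#' @param half_width Half-width in bp; the slice covers
#'   `[center - half_width, center + half_width)`, i.e. `2 * half_width`
#'   bases.
#' @return A [signal_track()] of length `2 * half_width`.
#' @export
extract_region <- function(track, center, half_width) {
  stopifnot(inherits(track, "signal_track"), half_width >= 1)
  lo <- center - half_width
  hi <- center + half_width - 1L
  first <- track$start
  last <- track$start + length(track$values) - 1L
  if (lo < first || hi > last)
    stop("requested region ", lo, "-", hi, " outside track ", first, "-",
         last)
  signal_track(track$chrom, lo,
               track$values[(lo - first + 1L):(hi - first + 1L)])
}
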