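## Interval arithmetic used by every downstream stage. Intervals are
## GRanges (1-based, closed, the Bioconductor convention); file readers
## convert from/to BED 0-based half-open coordinates. Strand is ignored
## throughout: features are treated strand-agnostically.

#' Construct a peak/feature GRanges from vectors
#'
#' Convenience constructor used by the simulator, readers, and tests.
#' Coordinates are 1-based closed (GRanges convention); use the readers in
#' this package for BED-style 0-based input.
#'
#' @param chrom Chromosome names.
#' @param start,end 1-based closed coordinates, `end >= start`.
#' @param strength Optional nonnegative peak score in -10*log10(p) units
#'   (MACS convention).
#' @param label Optional free-text labels.
#' @return A [GenomicRanges::GRanges] with optional `strength` and `label`
#'   metadata columns.
#' @examples
#' genomic_intervals("chrI", c(1, 50), c(20, 80), strength = c(30, 55))
#' @export
genomic_intervals <- function(chrom, start, end, strength = NULL,
                              label = NULL) {
  if (any(end < start)) stop("interval end < start")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  if (!is.null(strength)) {
    if (any(strength < 0, na.rm = TRUE))
      stop("peak strength must be nonnegative")
    S4Vectors::mcols(gr)$strength <- strength
  }
  if (!is.null(label)) S4Vectors::mcols(gr)$label <- label
  gr
}

#' Gap distance between genomic intervals
#'
#' Edge-to-edge gap in bp between pairs of intervals: 0 when they overlap
#' or are adjacent, `Inf` when they lie on different chromosomes.
#' Vectorized with the usual recycling rules.
#'
#' @param a,b `GRanges` of equal (or recyclable) length.
#' @return Numeric vector of distances (`Inf` across chromosomes).
#' @examples
#' a <- genomic_intervals("chrI", 11, 20)
#' b <- genomic_intervals("chrI", 26, 30)
#' interval_distance(a, b)  # 5
#' @export
interval_distance <- function(a, b) {
  d <- suppressWarnings(GenomicRanges::distance(a, b, ignore.strand = TRUE))
  d <- as.numeric(d)
  d[is.na(d)] <- Inf
  d
}

#' Windowed association of features with peaks
#'
#' A feature is associated when at least one peak lies within `window_bp`
#' of it (edge-to-edge gap, overlap counting as distance zero). A feature
#' associated with several peaks counts once: the statistic is the number
#' of associated features, not peak-feature pairs.
#'
#' @param features Nonempty `GRanges` of one annotation class.
#' @param peaks `GRanges` of peaks (may be empty).
#' @param window_bp Nonnegative association window in bp.
#' @return List with `associated` (logical per feature), `count`, `n`,
#'   and `fraction = count / n`.
#' @examples
#' f <- genomic_intervals("chrI", c(11, 51), c(20, 60))
#' p <- genomic_intervals("chrI", 26, 30)
#' associate_features(f, p, window_bp = 10)$associated  # TRUE FALSE
#' @export
associate_features <- function(features, peaks, window_bp) {
  if (length(features) == 0L)
    stop("empty feature set: association fraction undefined")
  stopifnot(window_bp >= 0)
  if (length(peaks) == 0L) {
    assoc <- rep(FALSE, length(features))
  } else {
    ## suppressed warning: disjoint seqlevels simply mean zero overlap
    assoc <- suppressWarnings(GenomicRanges::countOverlaps(
      features, peaks, maxgap = as.integer(window_bp),
      ignore.strand = TRUE)) > 0L
  }
  list(associated = assoc,
       count = sum(assoc),
       n = length(features),
       fraction = sum(assoc) / length(features))
}

#' Reciprocal windowed overlap counts between two interval sets
#'
#' Counts how many intervals of each set lie within `window_bp` of some
#' interval of the other set; each interval is counted at most once.
#'
#' @param set_a,set_b `GRanges`.
#' @param window_bp Nonnegative window in bp (0 = overlap/adjacency).
#' @return List with `n_a_hit` and `n_b_hit`.
#' @export
overlap_counts <- function(set_a, set_b, window_bp = 0) {
  stopifnot(window_bp >= 0)
  hit <- function(x, y) {
    if (length(x) == 0L || length(y) == 0L) return(0L)
    sum(suppressWarnings(
      GenomicRanges::countOverlaps(x, y, maxgap = as.integer(window_bp),
                                   ignore.strand = TRUE)) > 0L)
  }
  list(n_a_hit = hit(set_a, set_b), n_b_hit = hit(set_b, set_a))
}

#' Merge interval sets into maximal disjoint regions
#'
#' Per-base union of any number of interval sets, returned as the minimal
#' set of maximal disjoint regions, sorted by chromosome then start.
#' Adjacent intervals (gap zero) are merged, matching the per-base union.
#'
#' @param ... One or more `GRanges`.
#' @return A sorted, disjoint `GRanges` covering exactly the input bases.
#' @export
merge_union <- function(...) {
  sets <- list(...)
  sets <- lapply(sets, function(g) {
    S4Vectors::mcols(g) <- NULL
    g
  })
  all <- suppressWarnings(do.call(c, sets))  # sets may span different chroms
  GenomeInfoDb::seqlevels(all) <- sort(GenomeInfoDb::seqlevels(all))
  GenomicRanges::reduce(GenomicRanges::sort(all, ignore.strand = TRUE),
                        ignore.strand = TRUE)
}
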