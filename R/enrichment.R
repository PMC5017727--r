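## Permutation-based feature-association enrichment. The null model
## scrambles peak locations while preserving each peak's length,
## chromosome, and GC content (within a tolerance), placements uniform
## over qualifying start positions. The empirical p-value is the
## fraction of scrambled peak sets achieving at least the observed
## number of associated features; p-values below 1/N are reported as the
## bound "< 1/N", never as 0. One shared set of shuffles scores every
## feature class, so a full run is reproducible from a single seed.

#' GC fraction of intervals
#'
#' (#G + #C) / (#A + #C + #G + #T) over each interval; N bases are
#' excluded from numerator and denominator.
#'
#' @param genome `DNAStringSet`.
#' @param intervals `GRanges` within chromosome bounds.
#' @return Numeric vector of GC fractions.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chrI = "ACGTGGCC"))
#' gc_content(g, genomic_intervals("chrI", 1, 4))  # 0.5
#' @export
gc_content <- function(genome, intervals) {
  chrlen <- Biostrings::width(genome)
  names(chrlen) <- names(genome)
  ch <- as.character(GenomicRanges::seqnames(intervals))
  if (!all(ch %in% names(genome)))
    stop("interval chromosome(s) absent from genome: ",
         paste(unique(setdiff(ch, names(genome))), collapse = ", "))
  s <- GenomicRanges::start(intervals)
  e <- GenomicRanges::end(intervals)
  if (any(s < 1L) || any(e > chrlen[ch]))
    stop("interval out of chromosome bounds")
  out <- numeric(length(intervals))
  for (chrom in unique(ch)) {
    i <- which(ch == chrom)
    v <- Biostrings::Views(genome[[chrom]], start = s[i], end = e[i])
    freq <- Biostrings::letterFrequency(v, letters = c("CG", "AT"))
    denom <- freq[, "C|G"] + freq[, "A|T"]
    if (any(denom == 0))
      stop("interval consists entirely of N bases (index ",
           paste(i[denom == 0], collapse = ", "), ")")
    out[i] <- freq[, "C|G"] / denom
  }
  out
}

#' Sliding-window GC index for one window width
#'
#' GC fraction of every start position's window on each chromosome,
#' N bases excluded from numerator and denominator; all-N windows are
#' `NaN`. This is the index the matched shuffle samples from.
#'
#' @param genome `DNAStringSet`.
#' @param width Window width in bp (a peak length).
#' @return Named list (per chromosome) of numeric vectors of length
#'   `chromosome length - width + 1`.
#' @export
gc_window_index <- function(genome, width) {
  stopifnot(width >= 1)
  out <- lapply(seq_along(genome), function(i) {
    if (Biostrings::width(genome)[i] < width) return(numeric(0))
    m <- Biostrings::letterFrequencyInSlidingView(
      genome[[i]], width, letters = c("CG", "AT"))
    m[, "C|G"] / (m[, "C|G"] + m[, "A|T"])
  })
  names(out) <- names(genome)
  out
}

## Candidate start positions for one peak: windows of the peak's length
## on the peak's chromosome whose GC fraction is within `tolerance` of
## the peak's. If none qualify, the tolerance is doubled (up to
## `max_relax` times) before giving up; relaxations are counted in the
## returned attribute.
.gc_candidates <- function(gcvec, target, tolerance, max_relax = 5L,
                           peak_id = "?") {
  tol <- tolerance
  for (r in 0:max_relax) {
    cand <- which(!is.nan(gcvec) & abs(gcvec - target) <= tol)
    if (length(cand) > 0L)
      return(structure(cand, relaxations = r, tolerance = tol))
    tol <- 2 * tol
  }
  stop("no GC-matched position for peak ", peak_id,
       " (target GC ", signif(target, 3), ") within tolerance ",
       signif(tol / 2, 3), " after ", max_relax, " relaxations")
}

## Draw `n_draws` matched shuffles at once. Returns an integer matrix of
## start positions (peaks x draws); lengths and chromosomes are those of
## the input peaks. GC window indices are cached per (chromosome, length).
.gc_shuffle_starts <- function(peaks, genome, tolerance, n_draws) {
  ch <- as.character(GenomicRanges::seqnames(peaks))
  len <- GenomicRanges::width(peaks)
  target <- gc_content(genome, peaks)
  cache <- new.env(parent = emptyenv())
  starts <- matrix(0L, nrow = length(peaks), ncol = n_draws)
  relax <- integer(length(peaks))
  for (i in seq_along(peaks)) {
    key <- paste0(ch[i], ":", len[i])
    if (is.null(cache[[key]]))
      cache[[key]] <- gc_window_index(genome[ch[i]], len[i])[[1]]
    cand <- .gc_candidates(cache[[key]], target[i], tolerance,
                           peak_id = paste0(ch[i], ":",
                                            GenomicRanges::start(peaks)[i],
                                            "-",
                                            GenomicRanges::end(peaks)[i]))
    relax[i] <- attr(cand, "relaxations")
    starts[i, ] <- cand[sample.int(length(cand), n_draws, replace = TRUE)]
  }
  attr(starts, "relaxations") <- relax
  starts
}

#' One GC/length/chromosome-matched shuffle of a peak set
#'
#' Every output interval keeps the length and chromosome of its input
#' peak and has window GC within `tolerance` of the input peak's GC;
#' placement is uniform over all qualifying start positions. Shuffled
#' peaks may overlap each other and their original location (excluding
#' either would bias the null). If no position qualifies, the tolerance
#' is doubled, at most five times, before a per-peak error.
#'
#' @param peaks `GRanges`.
#' @param genome `DNAStringSet` covering the peaks' chromosomes.
#' @param tolerance Maximum absolute GC-fraction deviation (default
#'   0.02).
#' @return Shuffled `GRanges`, with per-peak relaxation counts in the
#'   `relaxations` metadata column (0 = matched at the requested
#'   tolerance).
#' @export
shuffle_gc_matched <- function(peaks, genome, tolerance = 0.02) {
  starts <- .gc_shuffle_starts(peaks, genome, tolerance, 1L)
  out <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(peaks),
    IRanges::IRanges(as.vector(starts[, 1]),
                     width = GenomicRanges::width(peaks)))
  S4Vectors::mcols(out)$relaxations <- attr(starts, "relaxations")
  out
}

#' Empirical permutation p-value
#'
#' `p = #\{permuted >= observed\} / N`. When no permutation reaches the
#' observed count the p-value is below the resolution of the test and is
#' flagged, to be reported as `"< 1/N"` rather than 0.
#'
#' @param observed Observed association count.
#' @param permuted Vector of permuted association counts (nonempty).
#' @return List with `p`, `below_resolution`, and a `display` string.
#' @examples
#' empirical_pvalue(6, c(3, 5, 7, 9))$p  # 0.5
#' @export
empirical_pvalue <- function(observed, permuted) {
  stopifnot(length(permuted) > 0)
  n <- length(permuted)
  k <- sum(permuted >= observed)
  below <- k == 0L
  list(p = k / n,
       below_resolution = below,
       display = if (below) paste0("< ", format(1 / n)) else
         format(k / n))
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error target.
#' @param n_tests Number of feature classes tested.
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 16)  # 0.003125, i.e. 0.003 to one figure
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}

#' Permutation enrichment of peak-feature associations
#'
#' For each feature class, counts the features with a peak within
#' `window_bp` and compares the count with the same statistic over
#' `config$n_permutations` GC/length/chromosome-matched shuffles of the
#' peak set. One shared set of shuffles scores every class. Significance
#' uses the Bonferroni threshold `alpha / #classes`.
#'
#' @param peaks `GRanges` peak set.
#' @param features Named list of `GRanges`, one per feature class.
#' @param genome `DNAStringSet`.
#' @param config An [analysis_config()].
#' @param window_bp Association window; defaults to
#'   `config$peak_window_bp` (use `config$damage_window_bp` for
#'   kilobase-scale damage marks).
#' @return A `data.frame` of class `"enrichment_result"` with one row per
#'   class: `feature`, `n_features`, `n_associated`, `fraction`,
#'   `p_value`, `p_display`, `below_resolution`, `significant`.
#'   Attributes: `perm_counts` (class x permutation matrix), `window_bp`,
#'   `threshold`.
#' @export
enrichment_analysis <- function(peaks, features, genome,
                                config = analysis_config(),
                                window_bp = config$peak_window_bp) {
  stopifnot(inherits(config, "analysis_config"),
            length(features) > 0, !is.null(names(features)))
  if (any(vapply(features, length, integer(1)) == 0L))
    stop("empty feature class: ",
         paste(names(features)[vapply(features, length, integer(1)) == 0],
               collapse = ", "))
  window_bp <- as.integer(window_bp)
  n_perm <- config$n_permutations
  chroms <- names(genome)
  ## per-chromosome IRanges of each class, and of the observed peaks
  f_by_chrom <- lapply(features, function(f) {
    ch <- as.character(GenomicRanges::seqnames(f))
    lapply(stats::setNames(chroms, chroms), function(cc)
      IRanges::IRanges(GenomicRanges::start(f)[ch == cc],
                       GenomicRanges::end(f)[ch == cc]))
  })
  count_assoc <- function(peak_ir_by_chrom) {
    vapply(f_by_chrom, function(fb) {
      tot <- 0L
      for (cc in chroms) {
        if (length(fb[[cc]]) == 0L || length(peak_ir_by_chrom[[cc]]) == 0L)
          next
        tot <- tot + sum(IRanges::countOverlaps(
          fb[[cc]], peak_ir_by_chrom[[cc]], maxgap = window_bp) > 0L)
      }
      tot
    }, integer(1))
  }
  pk_ch <- as.character(GenomicRanges::seqnames(peaks))
  obs_ir <- lapply(stats::setNames(chroms, chroms), function(cc)
    IRanges::IRanges(GenomicRanges::start(peaks)[pk_ch == cc],
                     GenomicRanges::end(peaks)[pk_ch == cc]))
  observed <- count_assoc(obs_ir)

  starts <- .gc_shuffle_starts(peaks, genome, config$gc_tolerance, n_perm)
  widths <- GenomicRanges::width(peaks)
  by_ch <- split(seq_along(peaks), pk_ch)
  perm_counts <- matrix(0L, nrow = length(features), ncol = n_perm,
                        dimnames = list(names(features), NULL))
  for (j in seq_len(n_perm)) {
    perm_ir <- lapply(stats::setNames(chroms, chroms), function(cc) {
      i <- by_ch[[cc]]
      if (is.null(i)) return(IRanges::IRanges())
      IRanges::IRanges(starts[i, j], width = widths[i])
    })
    perm_counts[, j] <- count_assoc(perm_ir)
  }
  threshold <- bonferroni_threshold(config$alpha, length(features))
  rows <- lapply(names(features), function(nm) {
    ep <- empirical_pvalue(observed[[nm]], perm_counts[nm, ])
    data.frame(feature = nm,
               n_features = length(features[[nm]]),
               n_associated = observed[[nm]],
               fraction = observed[[nm]] / length(features[[nm]]),
               p_value = ep$p,
               p_display = ep$display,
               below_resolution = ep$below_resolution,
               significant = ep$p < threshold,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  attr(res, "perm_counts") <- perm_counts
  attr(res, "window_bp") <- window_bp
  attr(res, "threshold") <- threshold
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Upper-tail hypergeometric comparison of association rates
#'
#' Probability of observing at least `k_hit_in_subset` associated
#' members in a subset of size `n_subset` drawn from a population of
#' `n_total` members of which `k_hit_total` are associated. Used, e.g.,
#' to ask whether highly expressed genes are associated more often than
#' expected from all genes.
#'
#' @param k_hit_in_subset,n_subset Hits in and size of the subset.
#' @param k_hit_total,n_total Hits in and size of the population
#'   (subset included).
#' @return Upper-tail p-value.
#' @examples
#' hypergeometric_rate_test(2, 2, 2, 4)  # 1/6
#' @export
hypergeometric_rate_test <- function(k_hit_in_subset, n_subset,
                                     k_hit_total, n_total) {
  if (n_subset > n_total || k_hit_in_subset > k_hit_total ||
      k_hit_in_subset > n_subset || k_hit_total > n_total ||
      (n_subset - k_hit_in_subset) > (n_total - k_hit_total) ||
      any(c(k_hit_in_subset, n_subset, k_hit_total, n_total) < 0))
    stop("incoherent counts: subset must be contained in the population")
  stats::phyper(k_hit_in_subset - 1, k_hit_total, n_total - k_hit_total,
                n_subset, lower.tail = FALSE)
}
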