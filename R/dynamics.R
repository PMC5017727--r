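## Cross-condition peak comparison: merged-region matching with
## zero-imputation for absent peaks, fraction-stronger, Wilcoxon
## signed-rank on paired strengths, per-feature stratification, and
## Venn overlap counts.

#' Match peaks across two conditions on merged regions
#'
#' Regions are the per-base union of both conditions' peaks; each region
#' carries, per condition, the maximum strength among that condition's
#' peaks overlapping it, or 0 when the condition has no peak there
#' (zero-imputation, so condition-specific peaks sit on an axis of the
#' strength scatter plot).
#'
#' @param peaks_a,peaks_b `GRanges` with a complete `strength` column.
#' @return `data.frame` of class `"region_matches"` with columns `chrom`,
#'   `start`, `end` (1-based closed), `strength_a`, `strength_b`.
#' @export
match_conditions <- function(peaks_a, peaks_b) {
  for (p in list(peaks_a, peaks_b)) {
    st <- S4Vectors::mcols(p)$strength
    if (is.null(st) || anyNA(st))
      stop("both peak tables must carry complete strengths")
  }
  regions <- merge_union(peaks_a, peaks_b)
  max_strength <- function(pk) {
    hits <- GenomicRanges::findOverlaps(regions, pk, ignore.strand = TRUE)
    out <- numeric(length(regions))
    if (length(hits) > 0) {
      agg <- tapply(S4Vectors::mcols(pk)$strength[S4Vectors::to(hits)],
                    S4Vectors::from(hits), max)
      out[as.integer(names(agg))] <- agg
    }
    out
  }
  res <- data.frame(chrom = as.character(GenomicRanges::seqnames(regions)),
                    start = GenomicRanges::start(regions),
                    end = GenomicRanges::end(regions),
                    strength_a = max_strength(peaks_a),
                    strength_b = max_strength(peaks_b),
                    stringsAsFactors = FALSE)
  class(res) <- c("region_matches", "data.frame")
  res
}

#' Fraction of matched regions stronger in condition B
#'
#' Strict inequality: ties are excluded from the numerator but stay in
#' the denominator. A region with a peak only in B (strength_a = 0)
#' counts as stronger.
#'
#' @param matches Output of [match_conditions()] (nonempty).
#' @return Fraction in \[0, 1\].
#' @export
fraction_stronger <- function(matches) {
  if (nrow(matches) == 0L) stop("no matched regions")
  mean(matches$strength_b > matches$strength_a)
}

#' Wilcoxon signed-rank test on matched peak strengths
#'
#' Two-sided signed-rank test on the paired differences
#' `strength_b - strength_a`. Zero differences are dropped (the Wilcoxon
#' convention). The exact distribution is used for n <= 25 untied
#' differences; otherwise the normal approximation with continuity
#' correction. p-values below 1e-50 are additionally flagged, mirroring
#' the convention of reporting them as "approximately 0".
#'
#' @param matches Output of [match_conditions()], or anything with
#'   `strength_a`/`strength_b` columns.
#' @return List with `p`, `approx_zero`, `n_used` (nonzero differences),
#'   and the signed-rank `statistic`.
#' @export
wilcoxon_paired <- function(matches) {
  d <- matches$strength_b - matches$strength_a
  d <- d[d != 0]
  if (length(d) == 0L)
    stop("all paired differences are zero; signed-rank test undefined")
  use_exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(stats::wilcox.test(d, exact = use_exact,
                                            correct = TRUE))
  list(p = wt$p.value,
       approx_zero = wt$p.value < 1e-50,
       n_used = length(d),
       statistic = unname(wt$statistic))
}

#' Restrict matched regions to those near a feature class
#'
#' @param matches Output of [match_conditions()].
#' @param features `GRanges` of one feature class.
#' @param window_bp Nonnegative association window in bp.
#' @return The subset of `matches` whose region lies within `window_bp`
#'   of some feature.
#' @export
stratify_by_feature <- function(matches, features, window_bp) {
  stopifnot(window_bp >= 0)
  if (length(features) == 0L) return(matches[integer(0), , drop = FALSE])
  regions <- GenomicRanges::GRanges(matches$chrom,
                                    IRanges::IRanges(matches$start,
                                                     matches$end))
  keep <- suppressWarnings(
    GenomicRanges::countOverlaps(regions, features,
                                 maxgap = as.integer(window_bp),
                                 ignore.strand = TRUE)) > 0L
  matches[keep, , drop = FALSE]
}

#' Venn overlap counts between two peak sets
#'
#' @param peaks_a,peaks_b `GRanges`.
#' @param window_bp Window for counting overlap (default 0 = direct
#'   overlap/adjacency).
#' @return List with `only_a`, `only_b`, `n_a_shared`, `n_b_shared`
#'   (the two intersection numbers: peaks of A overlapping some B peak,
#'   and vice versa).
#' @export
venn_counts <- function(peaks_a, peaks_b, window_bp = 0) {
  oc <- overlap_counts(peaks_a, peaks_b, window_bp)
  list(only_a = length(peaks_a) - oc$n_a_hit,
       only_b = length(peaks_b) - oc$n_b_hit,
       n_a_shared = oc$n_a_hit,
       n_b_shared = oc$n_b_hit)
}

#' Full two-condition comparison
#'
#' Convenience wrapper producing the quantities reported for a
#' wild-type/depleted pair: matched regions, fraction stronger in the
#' second condition, the signed-rank p, Venn counts, and optional
#' per-feature strata.
#'
#' @param peaks_a,peaks_b `GRanges` with strengths (A = reference, e.g.
#'   wild type; B = comparison, e.g. helicase-depleted).
#' @param features Optional named list of `GRanges` to stratify by.
#' @param window_bp Stratification window in bp.
#' @return List of class `"comparison_result"`: `matches`, `venn`,
#'   `overall` (n_regions, fraction_stronger_b, wilcoxon_p, approx_zero),
#'   and `strata` (a `data.frame`, one row per feature class).
#' @export
compare_conditions <- function(peaks_a, peaks_b, features = NULL,
                               window_bp = 300) {
  matches <- match_conditions(peaks_a, peaks_b)
  wt <- wilcoxon_paired(matches)
  overall <- data.frame(stratum = "all",
                        n_regions = nrow(matches),
                        fraction_stronger_b = fraction_stronger(matches),
                        wilcoxon_p = wt$p,
                        approx_zero = wt$approx_zero,
                        stringsAsFactors = FALSE)
  strata <- NULL
  if (!is.null(features)) {
    rows <- lapply(names(features), function(nm) {
      sub <- stratify_by_feature(matches, features[[nm]], window_bp)
      if (nrow(sub) == 0L || all(sub$strength_b == sub$strength_a))
        return(data.frame(stratum = nm, n_regions = nrow(sub),
                          fraction_stronger_b = NA_real_,
                          wilcoxon_p = NA_real_, approx_zero = NA,
                          stringsAsFactors = FALSE))
      swt <- wilcoxon_paired(sub)
      data.frame(stratum = nm, n_regions = nrow(sub),
                 fraction_stronger_b = fraction_stronger(sub),
                 wilcoxon_p = swt$p, approx_zero = swt$approx_zero,
                 stringsAsFactors = FALSE)
    })
    strata <- do.call(rbind, rows)
  }
  structure(list(matches = matches,
                 venn = venn_counts(peaks_a, peaks_b),
                 overall = overall,
                 strata = strata),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("comparison of %d matched regions\n", nrow(x$matches)))
  cat(sprintf("  venn: only_a=%d shared=%d/%d only_b=%d\n",
              x$venn$only_a, x$venn$n_a_shared, x$venn$n_b_shared,
              x$venn$only_b))
  p <- x$overall$wilcoxon_p
  cat(sprintf("  stronger in B: %.1f%%  (Wilcoxon p %s)\n",
              100 * x$overall$fraction_stronger_b,
              if (isTRUE(x$overall$approx_zero)) "~ 0" else
                format(p, digits = 3)))
  invisible(x)
}
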