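#' Analysis configuration
#'
#' Bundles the tunable constants used across the pipeline. Defaults follow
#' the conventions of windowed ChIP-seq peak annotation: protein-occupancy
#' peaks (helicase, DNA polymerase) are associated with a feature when they
#' lie within 300 bp of it (the typical ChIP shearing size), while
#' phospho-H2A damage marks, which spread over kilobase-scale domains, use a
#' 5 kb window.
#'
#' @param peak_window_bp Distance threshold (bp) for protein-peak
#'   association. Default 300.
#' @param damage_window_bp Distance threshold (bp) for damage-mark
#'   association. Default 5000.
#' @param n_permutations Number of matched shuffles for the permutation
#'   null. Default 1000, giving a p-value resolution of 0.001.
#' @param alpha Family-wise error target for Bonferroni correction.
#' @param gc_tolerance Maximum absolute deviation of shuffled-window GC
#'   fraction from the original peak's GC fraction. Default 0.02.
#' @param saint_threshold Interaction-confidence cutoff for IP-MS records
#'   (inclusive). Default 0.80.
#' @param hanning_bp Length (bp) of the Hanning smoothing window for
#'   signal tracks. Default 1000.
#' @param pseudocount Value added to IP and input coverage before the
#'   log2 ratio. Default 1.
#' @param seed Integer RNG seed used by pipeline orchestration, or `NULL`
#'   to leave the RNG state alone.
#'
#' @return A list of class `"analysis_config"`.
#' @examples
#' cfg <- analysis_config(n_permutations = 100)
#' cfg$peak_window_bp
#' @export
analysis_config <- function(peak_window_bp = 300,
                            damage_window_bp = 5000,
                            n_permutations = 1000,
                            alpha = 0.05,
                            gc_tolerance = 0.02,
                            saint_threshold = 0.80,
                            hanning_bp = 1000,
                            pseudocount = 1,
                            seed = NULL) {
  stopifnot(peak_window_bp >= 0, damage_window_bp > 0,
            n_permutations >= 1,
            alpha > 0, alpha < 1,
            gc_tolerance >= 0, gc_tolerance < 1,
            saint_threshold >= 0, saint_threshold <= 1,
            hanning_bp >= 3, pseudocount > 0)
  structure(list(peak_window_bp = as.integer(peak_window_bp),
                 damage_window_bp = as.integer(damage_window_bp),
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha,
                 gc_tolerance = gc_tolerance,
                 saint_threshold = saint_threshold,
                 hanning_bp = as.integer(hanning_bp),
                 pseudocount = pseudocount,
                 seed = seed),
            class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("analysis_config\n")
  for (nm in setdiff(names(x), "seed"))
    cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  cat(sprintf("  %-18s %s\n", "seed",
              if (is.null(x$seed)) "<none>" else format(x$seed)))
  invisible(x)
}
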