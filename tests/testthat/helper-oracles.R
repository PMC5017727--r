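## Independent brute-force oracles used across the suite. These stay
## deliberately naive (per-base enumeration, O(n*m) loops, DP over the
## signed-rank distribution) so they share no code path with the
## implementation they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

## shorthand GRanges constructor (1-based closed)
gr <- function(chrom, start, end, strength = NULL) {
  g <- GRanges(chrom, IRanges::IRanges(start, end))
  if (!is.null(strength)) g$strength <- strength
  g
}

## edge-to-edge gap between two single intervals, Inf across chromosomes
bf_gap <- function(c1, s1, e1, c2, s2, e2) {
  if (c1 != c2) return(Inf)
  if (s1 <= e2 && s2 <= e1) return(0)
  if (s1 > e2) s1 - e2 - 1 else s2 - e1 - 1
}

## all-pairs windowed association of features with peaks
bf_associated <- function(features, peaks, window) {
  fc <- as.character(seqnames(features))
  pc <- as.character(seqnames(peaks))
  vapply(seq_along(features), function(i) {
    any(vapply(seq_along(peaks), function(j)
      bf_gap(fc[i], start(features)[i], end(features)[i],
             pc[j], start(peaks)[j], end(peaks)[j]) <= window,
      logical(1)))
  }, logical(1))
}

## per-base union of interval sets -> data.frame(chrom, start, end)
bf_union <- function(...) {
  all <- do.call(c, lapply(list(...), function(g) {
    mcols(g) <- NULL
    g
  }))
  out <- NULL
  for (ch in sort(unique(as.character(seqnames(all))))) {
    sub <- all[seqnames(all) == ch]
    if (length(sub) == 0) next
    hi <- max(end(sub))
    covered <- rep(FALSE, hi)
    for (i in seq_along(sub)) covered[start(sub)[i]:end(sub)[i]] <- TRUE
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    out <- rbind(out, data.frame(chrom = ch, start = starts[keep],
                                 end = ends[keep]))
  }
  out
}

## exact two-sided signed-rank p-value via the generating-function DP
## over all 2^n sign assignments (untied |differences| assumed)
bf_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  stopifnot(!any(duplicated(rk)))
  v <- sum(rk[d > 0])
  maxw <- n * (n + 1) / 2
  f <- c(1, rep(0, maxw))  # f[w+1] = #assignments with W+ = w
  for (r in rk) {
    g <- f
    g[(r + 1):(maxw + 1)] <- g[(r + 1):(maxw + 1)] + f[1:(maxw + 1 - r)]
    f <- g
  }
  f <- f / 2^n
  lower <- sum(f[1:(v + 1)])
  upper <- sum(f[(v + 1):(maxw + 1)])
  min(1, 2 * min(lower, upper))
}

## direct O(n * k) convolution of a vector with a kernel, truncated and
## renormalized at the edges
bf_smooth <- function(x, w) {
  half <- (length(w) - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    ks <- max(1L, i - half):min(n, i + half)
    wk <- w[ks - i + half + 1L]
    sum(x[ks] * wk) / sum(wk)
  }, numeric(1))
}

## random interval set on a toy genome
random_intervals <- function(n, chroms = c("chrA", "chrB"), len = 1000,
                             max_width = 50) {
  ch <- sample(chroms, n, replace = TRUE)
  s <- sample.int(len - max_width, n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  gr(ch, s, s + w - 1L)
}

## small uniform-GC toy genome
toy_genome <- function(lens = c(chrA = 4000, chrB = 3000), seed = 99) {
  set.seed(seed)
  seqs <- vapply(lens, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
          collapse = ""), character(1))
  DNAStringSet(seqs)
}

## desk-scale simulation spec kept small enough for unit tests
small_spec <- function(seed = 3, ...) {
  args <- list(
    n_chromosomes = 2, chromosome_length_bp = 50000,
    feature_classes = data.frame(
      name = c("trna", "genes", "ndr"),
      n = c(15L, 40L, 25L),
      mean_length = c(80, 900, 150)),
    enrichment = c(trna = 20),
    n_peaks = c(pfh1 = 60, cdc20_wt = 50, cdc20_dep = 55,
                gh2a_wt = 20, gh2a_dep = 60),
    seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_spec, args)
}
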