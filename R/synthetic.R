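## Synthetic-data generator. Produces inputs with the statistical
## structure the analysis assumes: a small multi-chromosome genome with
## block-wise varying GC, sixteen annotation classes, peak sets planted
## with configurable enrichment near chosen classes and configurable
## cross-condition sharing and strength shifts, per-base IP/input
## coverage, and bait-versus-control spectral counts for S and G2 phase.
## Everything is deterministic given `spec$seed`; each generator derives
## its own substream (seed + fixed offset) so stages can be re-run
## independently with identical results.

#' Default desk-scale feature classes
#'
#' Sixteen annotation classes mirroring the composition of a fission-yeast
#' annotation set (tRNA and 5S rRNA genes, highly expressed genes,
#' coding genes, UTRs, promoters, nucleosome-depleted regions, origins,
#' meiotic DSB hotspots, G4 motifs, ...), with counts scaled to a 600 kb
#' desk genome.
#'
#' @return `data.frame` with columns `name`, `n`, `mean_length`.
#' @export
default_feature_classes <- function() {
  data.frame(
    name = c("trna", "rrna_5s", "top_expressed", "pol2_genes", "cds",
             "dubious", "utr3", "utr5", "promoters", "ndr", "origins",
             "dsb_hotspots", "g4_motifs", "ltr", "mating_type",
             "centromere"),
    n = c(40L, 12L, 50L, 220L, 300L, 8L, 220L, 220L, 180L, 120L, 40L,
          25L, 30L, 15L, 2L, 3L),
    mean_length = c(80, 120, 1500, 1400, 1200, 400, 200, 150, 300, 150,
                    600, 1200, 30, 350, 3000, 5000),
    stringsAsFactors = FALSE)
}

#' Simulation specification
#'
#' Defines the study conditions the generator emulates. The per-condition
#' peak counts default to the deposited peak-set sizes of the motivating
#' study (621 helicase peaks; 485/517 polymerase-occupancy peaks in
#' wild-type/depleted cells; 179/582 damage-mark peaks), and the
#' depleted-condition strength shifts are derived so that the expected
#' fraction of matched regions stronger after depletion reproduces the
#' reported 64% (polymerase) and 88% (damage mark); the derivation is in
#' the methods vignette.
#'
#' @param n_chromosomes,chromosome_length_bp Genome shape. Default 3 x
#'   200 kb, which keeps a 1000-permutation enrichment run fast.
#' @param gc_block_bp Length of constant-GC blocks.
#' @param gc_range Per-block GC-fraction targets are drawn uniformly from
#'   this range.
#' @param feature_classes `data.frame(name, n, mean_length)`; see
#'   [default_feature_classes()].
#' @param enrichment Named weights (>= 1) for peak placement near the
#'   named classes; unnamed classes have weight 1.
#' @param enrichment_window_bp Half-width of the enriched footprint
#'   around each feature of a weighted class.
#' @param n_peaks Named integer vector of peak counts per condition;
#'   names `pfh1`, `cdc20_wt`, `cdc20_dep`, `gh2a_wt`, `gh2a_dep`.
#' @param peak_mean_length_bp Mean peak length (lognormal, sdlog 0.3).
#' @param share_fraction Fraction of wild-type peaks re-used verbatim in
#'   the matching depleted condition (controls Venn overlap).
#' @param strength_depth,strength_fold Poisson depths of the binomial
#'   strength model: IP ~ Pois(fold * depth) inside a peak versus
#'   input ~ Pois(depth); strength = -10*log10 of the one-sided binomial
#'   tail, the MACS scale.
#' @param strength_shift Named additive shifts (`cdc20`, `gh2a`) applied
#'   to re-used peaks in the depleted condition.
#' @param strength_noise_sd Per-condition strength noise; the paired
#'   difference of a re-used peak is shift + N(0, sqrt(2) * sd).
#' @param coverage_depth,coverage_fold Per-base Poisson coverage depths
#'   (input, and IP fold change inside peaks).
#' @param n_proteins,frac_true_interactors,bait_mean,ctrl_mean
#'   Spectral-count model: number of proteins, fraction that are true
#'   bait interactors, and per-replicate Poisson means for bait and
#'   control counts.
#' @param g2_depletion_factor Multiplier on bait means in G2 phase for
#'   true interactors (0 makes every true interactor S-phase-limited).
#' @param pax_missing_fraction Fraction of proteins absent from the
#'   simulated proteome-abundance table.
#' @param seed Integer master seed.
#' @return List of class `"simulation_spec"`.
#' @export
simulation_spec <- function(n_chromosomes = 3,
                            chromosome_length_bp = 200000,
                            gc_block_bp = 10000,
                            gc_range = c(0.30, 0.50),
                            feature_classes = default_feature_classes(),
                            enrichment = c(trna = 20, rrna_5s = 20,
                                           top_expressed = 5, ndr = 3,
                                           dsb_hotspots = 3),
                            enrichment_window_bp = 300,
                            n_peaks = c(pfh1 = 621, cdc20_wt = 485,
                                        cdc20_dep = 517, gh2a_wt = 179,
                                        gh2a_dep = 582),
                            peak_mean_length_bp = 300,
                            share_fraction = 0.8,
                            strength_depth = 50,
                            strength_fold = 4,
                            strength_shift = c(cdc20 = 3.3, gh2a = 4.4),
                            strength_noise_sd = 5,
                            coverage_depth = 100,
                            coverage_fold = 4,
                            n_proteins = 100,
                            frac_true_interactors = 0.2,
                            bait_mean = 30,
                            ctrl_mean = 2,
                            g2_depletion_factor = 0.4,
                            pax_missing_fraction = 0.05,
                            seed = 1) {
  stopifnot(n_chromosomes >= 1, chromosome_length_bp > 0,
            gc_block_bp > 0, length(gc_range) == 2,
            all(gc_range >= 0), all(gc_range <= 1),
            all(feature_classes$n > 0),
            all(feature_classes$mean_length > 0),
            all(enrichment >= 1),
            all(names(enrichment) %in% feature_classes$name),
            all(n_peaks > 0),
            share_fraction >= 0, share_fraction <= 1,
            strength_depth > 0, strength_fold > 0,
            strength_noise_sd >= 0, coverage_depth > 0,
            coverage_fold > 0, n_proteins > 0,
            frac_true_interactors > 0, frac_true_interactors <= 1,
            bait_mean > 0, ctrl_mean >= 0,
            g2_depletion_factor >= 0,
            pax_missing_fraction >= 0, pax_missing_fraction < 1)
  spec <- as.list(environment())
  structure(spec, class = "simulation_spec")
}

.with_substream <- function(seed, offset, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed + offset)
  }
  expr
}

#' Generate a genome with block-wise varying GC
#'
#' Bases are drawn i.i.d. within fixed-length blocks whose GC targets are
#' uniform on `spec$gc_range`; at the default 10 kb block length the
#' empirical block GC lies within 0.05 of its target with overwhelming
#' probability.
#'
#' @param spec A [simulation_spec()].
#' @return `DNAStringSet` with attribute `gc_targets` (per-chromosome
#'   numeric vectors of block targets).
#' @export
make_genome <- function(spec) {
  .with_substream(spec$seed, 1L, {
    len <- as.integer(spec$chromosome_length_bp)
    bl <- as.integer(spec$gc_block_bp)
    targets <- list()
    seqs <- character(spec$n_chromosomes)
    for (i in seq_len(spec$n_chromosomes)) {
      starts <- seq(1L, len, by = bl)
      gc <- stats::runif(length(starts), spec$gc_range[1], spec$gc_range[2])
      targets[[i]] <- gc
      chunks <- vapply(seq_along(starts), function(j) {
        n <- min(bl, len - starts[j] + 1L)
        g <- gc[j]
        paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                     prob = c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2)),
              collapse = "")
      }, character(1))
      seqs[i] <- paste(chunks, collapse = "")
    }
    names(seqs) <- paste0("chr", utils::as.roman(seq_len(spec$n_chromosomes)))
    genome <- Biostrings::DNAStringSet(seqs)
    names(targets) <- names(seqs)
    attr(genome, "gc_targets") <- targets
    genome
  })
}

#' Generate annotation feature sets
#'
#' Each class is placed uniformly at random (chromosome chosen
#' proportionally to length), with lognormal length scatter around the
#' class mean. Classes may overlap one another, as real annotations do.
#'
#' @param spec A [simulation_spec()].
#' @param genome Genome from [make_genome()].
#' @return Named list of `GRanges`, one per feature class.
#' @export
make_features <- function(spec, genome) {
  .with_substream(spec$seed, 2L, {
    chrlen <- Biostrings::width(genome)
    chrnames <- names(genome)
    out <- list()
    for (k in seq_len(nrow(spec$feature_classes))) {
      cls <- spec$feature_classes[k, ]
      lens <- pmax(20L, round(cls$mean_length *
                                exp(stats::rnorm(cls$n, 0, 0.2))))
      lens <- pmin(lens, min(chrlen) - 1L)
      chrom <- sample(seq_along(chrnames), cls$n, replace = TRUE,
                      prob = chrlen)
      start <- vapply(seq_len(cls$n), function(i)
        sample.int(chrlen[chrom[i]] - lens[i] + 1L, 1L), integer(1))
      gr <- GenomicRanges::GRanges(chrnames[chrom],
                                   IRanges::IRanges(start,
                                                    width = lens))
      out[[cls$name]] <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    }
    out
  })
}

## Peak strengths on the MACS scale: -10*log10 of the upper binomial tail
## of IP counts against IP+input at p = 0.5.
.draw_strengths <- function(n, depth, fold) {
  ip <- stats::rpois(n, fold * depth)
  inp <- stats::rpois(n, depth)
  p <- stats::pbinom(ip - 1, ip + inp, 0.5, lower.tail = FALSE)
  pmax(0, -10 * log10(pmax(p, 1e-320)))
}

## Per-chromosome placement weights: background 1, enriched-class
## footprints (feature +/- enrichment_window_bp) get the class weight;
## overlapping footprints take the maximum.
.placement_weights <- function(spec, genome, features) {
  chrlen <- Biostrings::width(genome)
  names(chrlen) <- names(genome)
  w <- lapply(chrlen, function(l) rep(1, l))
  enr <- spec$enrichment[order(spec$enrichment)]
  for (nm in names(enr)) {
    foot <- GenomicRanges::reduce(
      GenomicRanges::resize(features[[nm]],
                            GenomicRanges::width(features[[nm]]) +
                              2L * spec$enrichment_window_bp,
                            fix = "center"))
    for (i in seq_along(foot)) {
      ch <- as.character(GenomicRanges::seqnames(foot)[i])
      s <- max(1L, GenomicRanges::start(foot)[i])
      e <- min(chrlen[[ch]], GenomicRanges::end(foot)[i])
      w[[ch]][s:e] <- pmax(w[[ch]][s:e], enr[[nm]])
    }
  }
  w
}

## Place n non-overlapping peaks with start positions sampled from the
## concatenated weight vector. `occupied` carries footprints of peaks the
## track must also avoid (e.g. re-used wild-type peaks).
.place_peaks <- function(n, lengths, weights, chrlen, occupied = NULL) {
  chrnames <- names(chrlen)
  offs <- c(0, cumsum(as.numeric(chrlen)))
  wall <- unlist(weights, use.names = FALSE)
  if (is.null(occupied))
    occupied <- lapply(chrlen, function(l) rep(FALSE, l))
  chrom <- integer(n); start <- integer(n)
  placed <- 0L; tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > 200L)
      stop("could not place ", n, " non-overlapping peaks; ",
           "genome too crowded")
    idx <- sample.int(length(wall), size = 2L * (n - placed),
                      replace = TRUE, prob = wall)
    for (g in idx) {
      if (placed >= n) break
      ch <- findInterval(g - 1L, offs)  # offs[ch] < g <= offs[ch+1]
      s <- g - offs[ch]
      L <- lengths[placed + 1L]
      e <- s + L - 1L
      if (e > chrlen[[ch]]) next
      if (any(occupied[[ch]][s:e])) next
      occupied[[ch]][s:e] <- TRUE
      placed <- placed + 1L
      chrom[placed] <- ch
      start[placed] <- s
    }
  }
  list(gr = GenomicRanges::sort(
    GenomicRanges::GRanges(chrnames[chrom],
                           IRanges::IRanges(start, width = lengths)),
    ignore.strand = TRUE),
    occupied = occupied)
}

#' Plant peak sets for every condition
#'
#' Peaks are placed with probability proportional to the enrichment
#' weight of the footprint they fall in and uniformly elsewhere; peaks
#' within one condition never overlap (as in merged peak-caller output).
#' For each wild-type/depleted pair, `share_fraction` of the wild-type
#' peaks are re-used verbatim in the depleted condition with strengths
#' shifted by the configured condition shift plus noise; the remaining
#' depleted peaks are planted fresh, avoiding the entire wild-type
#' track (a depleted-specific peak is by definition a site without a
#' wild-type peak), so the planted Venn overlap is exactly the number
#' of re-used peaks.
#'
#' @param spec A [simulation_spec()].
#' @param genome Genome from [make_genome()].
#' @param features Feature list from [make_features()] on this genome.
#' @return Named list of `GRanges` peak tables (with `strength` columns
#'   and a `condition` entry in `S4Vectors::metadata`), one per condition
#'   named in `spec$n_peaks`.
#' @export
plant_peaks <- function(spec, genome, features) {
  .with_substream(spec$seed, 3L, {
    chrlen <- Biostrings::width(genome)
    names(chrlen) <- names(genome)
    weights <- .placement_weights(spec, genome, features)
    draw_lengths <- function(n)
      pmax(50L, pmin(round(spec$peak_mean_length_bp *
                             exp(stats::rnorm(n, 0, 0.3))),
                     min(chrlen) - 1L))
    fresh <- function(n) {
      pl <- .place_peaks(n, draw_lengths(n), weights, chrlen)
      gr <- pl$gr
      S4Vectors::mcols(gr)$strength <-
        .draw_strengths(n, spec$strength_depth, spec$strength_fold)
      gr
    }
    out <- list()
    wt_of <- c(cdc20_dep = "cdc20_wt", gh2a_dep = "gh2a_wt")
    shift_of <- c(cdc20_dep = "cdc20", gh2a_dep = "gh2a")
    for (cond in names(spec$n_peaks)) {
      n <- as.integer(spec$n_peaks[[cond]])
      if (!cond %in% names(wt_of)) {
        out[[cond]] <- fresh(n)
        next
      }
      wt <- out[[wt_of[[cond]]]]
      n_share <- min(round(spec$share_fraction * length(wt)), n)
      keep <- sort(sample.int(length(wt), n_share))
      reused <- wt[keep]
      delta <- spec$strength_shift[[shift_of[[cond]]]]
      S4Vectors::mcols(reused)$strength <- pmax(
        0, reused$strength + delta +
          stats::rnorm(n_share, 0, sqrt(2) * spec$strength_noise_sd))
      ## block out every wild-type peak (with a 1 bp margin so new
      ## depleted peaks are not even adjacent to one)
      occ <- lapply(chrlen, function(l) rep(FALSE, l))
      for (i in seq_along(wt)) {
        ch <- as.character(GenomicRanges::seqnames(wt)[i])
        s <- max(1L, GenomicRanges::start(wt)[i] - 1L)
        e <- min(chrlen[[ch]], GenomicRanges::end(wt)[i] + 1L)
        occ[[ch]][s:e] <- TRUE
      }
      n_new <- n - n_share
      pl <- .place_peaks(n_new, draw_lengths(n_new), weights, chrlen, occ)
      new <- pl$gr
      S4Vectors::mcols(new)$strength <-
        .draw_strengths(n_new, spec$strength_depth, spec$strength_fold)
      gr <- GenomicRanges::sort(c(reused, new), ignore.strand = TRUE)
      out[[cond]] <- gr
    }
    for (cond in names(out))
      S4Vectors::metadata(out[[cond]])$condition <- cond
    out
  })
}

#' Simulate per-base IP and input coverage
#'
#' Input counts are Poisson(depth) everywhere; IP counts are
#' Poisson(depth * fold) inside peaks and Poisson(depth) elsewhere.
#'
#' @param genome `DNAStringSet` (only chromosome lengths are used).
#' @param peaks `GRanges` of enriched regions.
#' @param depth Mean input coverage per base.
#' @param fold IP fold enrichment inside peaks.
#' @param seed Optional seed (set before drawing).
#' @param chroms Chromosomes to simulate (default: all).
#' @return List with elements `ip` and `input`, each a named list of
#'   integer vectors, one per chromosome.
#' @export
simulate_coverage <- function(genome, peaks, depth = 100, fold = 4,
                              seed = NULL, chroms = names(genome)) {
  stopifnot(depth > 0, fold > 0)
  if (!is.null(seed)) set.seed(seed)
  chrlen <- Biostrings::width(genome)
  names(chrlen) <- names(genome)
  ip <- list(); input <- list()
  for (ch in chroms) {
    lambda <- rep(depth, chrlen[[ch]])
    pk <- peaks[GenomicRanges::seqnames(peaks) == ch]
    for (i in seq_along(pk)) {
      s <- GenomicRanges::start(pk)[i]
      e <- min(chrlen[[ch]], GenomicRanges::end(pk)[i])
      lambda[s:e] <- depth * fold
    }
    ip[[ch]] <- stats::rpois(chrlen[[ch]], lambda)
    input[[ch]] <- stats::rpois(chrlen[[ch]], depth)
  }
  list(ip = ip, input = input)
}

#' Simulate bait-versus-control spectral counts for S and G2 phase
#'
#' True interactors receive bait counts far above control counts and
#' surrogate confidence scores near 1 (Beta(20, 1.5)); non-interactors
#' receive background counts in both channels and scores near 0
#' (Beta(1.5, 20)). In G2 phase the bait means of true interactors are
#' multiplied by `g2_depletion_factor`, so with small factors some true
#' interactors drop to zero G2 counts (S-phase-limited) while others are
#' merely S-phase-enriched. Two replicates per channel.
#'
#' @param spec A [simulation_spec()].
#' @return List with `s` and `g2` spectral-count `data.frame`s, a named
#'   `pax` abundance vector (with a fraction of proteins missing), and
#'   the logical ground-truth vector `truth`.
#' @export
simulate_spectral_counts <- function(spec) {
  .with_substream(spec$seed, 5L, {
    n <- spec$n_proteins
    ids <- sprintf("prot%03d", seq_len(n))
    len <- pmax(50L, round(stats::rlnorm(n, log(450), 0.4)))
    truth <- seq_len(n) <= round(spec$frac_true_interactors * n)
    truth <- sample(truth)
    draw <- function(mean_true, mean_false)
      stats::rpois(n, ifelse(truth, mean_true, mean_false))
    score <- ifelse(truth, stats::rbeta(n, 20, 1.5),
                    stats::rbeta(n, 1.5, 20))
    s <- data.frame(protein_id = ids, length_aa = len,
                    bait_1 = draw(spec$bait_mean, spec$ctrl_mean),
                    bait_2 = draw(spec$bait_mean, spec$ctrl_mean),
                    ctrl_1 = stats::rpois(n, spec$ctrl_mean),
                    ctrl_2 = stats::rpois(n, spec$ctrl_mean),
                    saint_score = round(score, 3),
                    stringsAsFactors = FALSE)
    g2_mean <- spec$g2_depletion_factor * spec$bait_mean
    g2 <- data.frame(protein_id = ids, length_aa = len,
                     bait_1 = draw(g2_mean, spec$ctrl_mean),
                     bait_2 = draw(g2_mean, spec$ctrl_mean),
                     ctrl_1 = stats::rpois(n, spec$ctrl_mean),
                     ctrl_2 = stats::rpois(n, spec$ctrl_mean),
                     saint_score = round(ifelse(truth & g2_mean > 0,
                                                stats::rbeta(n, 20, 1.5),
                                                stats::rbeta(n, 1.5, 20)),
                                         3),
                     stringsAsFactors = FALSE)
    pax <- stats::setNames(stats::rlnorm(n, log(100), 1), ids)
    n_miss <- round(spec$pax_missing_fraction * n)
    if (n_miss > 0) pax <- pax[-sample.int(n, n_miss)]
    list(s = s, g2 = g2, pax = pax, truth = stats::setNames(truth, ids))
  })
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Generates genome, features, peaks, coverage (first chromosome, helicase
#' track), and spectral counts, and writes them as FASTA, BED, and TSV.
#'
#' @param spec A [simulation_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
simulate_bundle <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genome <- make_genome(spec)
  features <- make_features(spec, genome)
  peaks <- plant_peaks(spec, genome, features)
  counts <- simulate_spectral_counts(spec)
  cov <- simulate_coverage(genome, peaks$pfh1, depth = spec$coverage_depth,
                           fold = spec$coverage_fold,
                           seed = if (is.null(spec$seed)) NULL else
                             spec$seed + 4L,
                           chroms = names(genome)[1])
  paths <- list(genome = file.path(dir, "genome.fa"))
  write_genome(genome, paths$genome)
  for (nm in names(features)) {
    p <- file.path(dir, paste0("features_", nm, ".bed"))
    write_intervals_bed(features[[nm]], p)
    paths[[paste0("features_", nm)]] <- p
  }
  for (nm in names(peaks)) {
    p <- file.path(dir, paste0("peaks_", nm, ".tsv"))
    write_peak_table(peaks[[nm]], p)
    paths[[paste0("peaks_", nm)]] <- p
  }
  ch1 <- names(genome)[1]
  cov_df <- data.frame(chrom = ch1, pos = seq_along(cov$ip[[ch1]]) - 1L,
                       ip = cov$ip[[ch1]], input = cov$input[[ch1]])
  paths$coverage <- file.path(dir, "coverage_pfh1_chrI.tsv")
  utils::write.table(cov_df, paths$coverage, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$counts_s <- file.path(dir, "spectral_counts_s.tsv")
  paths$counts_g2 <- file.path(dir, "spectral_counts_g2.tsv")
  write_results(counts$s, paths$counts_s)
  write_results(counts$g2, paths$counts_g2)
  paths$pax <- file.path(dir, "pax.tsv")
  write_results(data.frame(protein_id = names(counts$pax),
                           pax = unname(counts$pax)), paths$pax)
  invisible(list(genome = genome, features = features, peaks = peaks,
                 coverage = cov, spectral = counts, paths = paths))
}
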