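test_that("genome generation is deterministic and hits block GC targets", {
  spec <- small_spec(seed = 5)
  g1 <- make_genome(spec)
  g2 <- make_genome(spec)
  expect_identical(as.character(g1), as.character(g2))
  g3 <- make_genome(small_spec(seed = 6))
  expect_false(identical(as.character(g1), as.character(g3)))

  targets <- attr(g1, "gc_targets")
  for (ch in names(g1)) {
    bl <- spec$gc_block_bp
    len <- Biostrings::width(g1)[names(g1) == ch]
    starts <- seq(1L, len, by = bl)
    ends <- pmin(starts + bl - 1L, len)
    emp <- gc_content(g1, gr(ch, starts, ends))
    expect_true(all(abs(emp - targets[[ch]]) < 0.05))
  }
})

test_that("planted peaks honor counts, non-overlap, and sharing", {
  spec <- small_spec(seed = 8)
  g <- make_genome(spec)
  f <- make_features(spec, g)
  p <- plant_peaks(spec, g, f)
  expect_equal(vapply(p, length, integer(1)),
               vapply(spec$n_peaks, as.integer, integer(1)))
  for (cond in names(p)) {
    expect_true(all(p[[cond]]$strength >= 0))
    ## no within-condition overlap (merged peak-caller convention)
    expect_equal(length(merge_union(p[[cond]])), length(p[[cond]]))
  }
  ## depleted tracks re-use exactly round(share * n_wt) wild-type peaks
  n_share <- round(spec$share_fraction * length(p$cdc20_wt))
  v <- venn_counts(p$cdc20_wt, p$cdc20_dep)
  expect_gte(v$n_a_shared, n_share)
  expect_lte(v$n_a_shared - n_share, 2)  # rare window-0 adjacency only
  expect_equal(v$only_a + v$n_a_shared, length(p$cdc20_wt))
  expect_equal(v$only_b + v$n_b_shared, length(p$cdc20_dep))
})

test_that("peak placement follows the enrichment weights", {
  spec <- small_spec(seed = 12)
  g <- make_genome(spec)
  f <- make_features(spec, g)
  p <- plant_peaks(spec, g, f)
  ## weight-20 class: most features should have a nearby peak; the
  ## weight-1 classes sit near the uniform expectation
  trna <- associate_features(f$trna, p$pfh1, 300)
  expect_gt(trna$fraction, 0.8)
})

test_that("coverage simulation is unbiased off-peak and enriched in-peak", {
  g <- toy_genome(c(chrT = 20000))
  cov0 <- simulate_coverage(g, gr("chrT", 1, 2)[0], depth = 100, seed = 2)
  t0 <- log2_ratio(cov0$ip$chrT, cov0$input$chrT)
  expect_lt(abs(mean(t0$values)), 0.05)

  cov1 <- simulate_coverage(g, gr("chrT", 9000, 9500), depth = 100,
                            fold = 4, seed = 2)
  sm <- hanning_smooth(log2_ratio(cov1$ip$chrT, cov1$input$chrT), 1000)
  peakpos <- which.max(sm$values)
  expect_gte(peakpos, 9000 - 250)
  expect_lte(peakpos, 9500 + 250)

  cov2 <- simulate_coverage(g, gr("chrT", 9000, 9500), depth = 100,
                            fold = 4, seed = 2)
  expect_identical(cov1$ip$chrT, cov2$ip$chrT)
})

test_that("spectral-count simulation encodes phase dependence and truth", {
  spec0 <- small_spec(seed = 9, g2_depletion_factor = 0)
  sc0 <- simulate_spectral_counts(spec0)
  pc0 <- phase_comparison(sc0$s, sc0$g2)
  truth0 <- sc0$truth[pc0$protein_id]
  expect_true(all(pc0$phase_class[truth0] == "S-limited"))

  spec4 <- small_spec(seed = 9, g2_depletion_factor = 0.4)
  sc4 <- simulate_spectral_counts(spec4)
  pc4 <- phase_comparison(sc4$s, sc4$g2)
  truth4 <- sc4$truth[pc4$protein_id]
  expect_gt(mean(pc4$phase_class[truth4] == "S-enriched"), 0.9)

  ## the 0.80 confidence cutoff recovers the planted interactors
  kept <- saint_filter(sc4$s, 0.80)
  truth_kept <- sc4$truth[kept$protein_id]
  recall <- sum(truth_kept) / sum(sc4$truth)
  fdr <- if (nrow(kept) > 0) mean(!truth_kept) else 0
  expect_gte(recall, 0.9)
  expect_lte(fdr, 0.1)
})

test_that("bundle files on disk reproduce the in-memory objects", {
  spec <- small_spec(seed = 4)
  dir <- tempfile("bundle_")
  b <- simulate_bundle(spec, dir)
  g <- read_genome(b$paths$genome)
  expect_equal(as.character(g), as.character(b$genome))
  pk <- read_peak_table(b$paths$peaks_pfh1, "pfh1")
  expect_equal(length(pk), length(b$peaks$pfh1))
  expect_equal(start(pk), start(b$peaks$pfh1))
  expect_equal(round(pk$strength, 4), round(b$peaks$pfh1$strength, 4))
  fb <- read_intervals(b$paths$features_trna, "bed")
  expect_equal(start(fb), start(b$features$trna))
})
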