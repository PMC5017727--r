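test_that("GC content counts G+C over non-N bases", {
  g <- Biostrings::DNAStringSet(c(chrI = "ATATGGCCACGTNNGG"))
  expect_equal(gc_content(g, gr("chrI", 1, 4)), 0)    # ATAT
  expect_equal(gc_content(g, gr("chrI", 5, 8)), 1)    # GGCC
  expect_equal(gc_content(g, gr("chrI", 9, 12)), 0.5) # ACGT
  ## Ns excluded from numerator and denominator
  expect_equal(gc_content(g, gr("chrI", 12, 16)), 2 / 3)  # TNNGG
  expect_error(gc_content(g, gr("chrI", 13, 14)), "entirely of N")
  expect_error(gc_content(g, gr("chrI", 10, 20)), "bounds")
  expect_error(gc_content(g, gr("chrX", 1, 4)), "absent")
})

test_that("sliding GC index matches direct per-window computation", {
  g <- toy_genome(c(chrA = 300))
  idx <- gc_window_index(g, 25)
  expect_length(idx$chrA, 300 - 25 + 1)
  starts <- c(1, 50, 276)
  expect_equal(idx$chrA[starts],
               gc_content(g, gr("chrA", starts, starts + 24)))
})

test_that("matched shuffle preserves length, chromosome, and GC", {
  g <- toy_genome(seed = 21)
  set.seed(22)
  peaks <- random_intervals(50, chroms = names(g), len = 2900,
                            max_width = 60)
  target <- gc_content(g, peaks)
  for (i in 1:20) {
    sh <- shuffle_gc_matched(peaks, g, tolerance = 0.02)
    expect_identical(width(sh), width(peaks))
    expect_identical(as.character(seqnames(sh)),
                     as.character(seqnames(peaks)))
    expect_true(all(abs(gc_content(g, sh) - target) <= 0.02))
    expect_true(all(sh$relaxations == 0))
  }
})

test_that("a unique qualifying window is always chosen", {
  seqs <- paste0(strrep("A", 500), "GGGG", strrep("A", 496))
  g <- Biostrings::DNAStringSet(c(chrZ = seqs))
  peak <- gr("chrZ", 501, 504)  # the only all-GC window of width 4
  for (i in 1:5) {
    sh <- shuffle_gc_matched(peak, g, tolerance = 0.02)
    expect_equal(start(sh), 501)
    expect_equal(sh$relaxations, 0L)
  }
  ## a peak's own window always qualifies, so the relaxation schedule
  ## and its terminal error are only reachable on the candidate finder
  cand <- helipeak:::.gc_candidates(c(0.5, 0.72, 0.5), 0.8, 0.01)
  expect_equal(as.integer(cand), 2L)
  expect_gte(attr(cand, "relaxations"), 1L)
  expect_error(helipeak:::.gc_candidates(c(0, 0, 0), 1, 0.01),
               "no GC-matched position")
})

test_that("empirical p-value follows its definition and reports bounds", {
  expect_equal(empirical_pvalue(6, c(3, 5, 7, 9))$p, 0.5)
  expect_equal(empirical_pvalue(0, c(0, 1, 2))$p, 1)
  top <- empirical_pvalue(10, rep(5, 1000))
  expect_equal(top$p, 0)
  expect_true(top$below_resolution)
  expect_match(top$display, "^< 0.001")
  ## antitone in the observed count, and p * N is an integer
  set.seed(30)
  perm <- rpois(500, 8)
  ps <- vapply(0:20, function(o) empirical_pvalue(o, perm)$p, numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_true(all(abs(ps * 500 - round(ps * 500)) < 1e-12))
})

test_that("Bonferroni threshold is alpha over the number of tests", {
  expect_equal(bonferroni_threshold(0.05, 16), 0.003125)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 10), 0.005)
})

test_that("hypergeometric rate comparison matches closed forms", {
  expect_equal(hypergeometric_rate_test(2, 2, 2, 4), 1 / 6)
  expect_equal(hypergeometric_rate_test(5, 10, 5, 10), 1)
  expect_equal(hypergeometric_rate_test(0, 3, 4, 10), 1)
  expect_error(hypergeometric_rate_test(3, 2, 5, 10), "incoherent")
  expect_error(hypergeometric_rate_test(1, 11, 5, 10), "incoherent")
})

test_that("with GC matching disabled the null matches uniform placement", {
  set.seed(77)
  g <- toy_genome(c(chrU = 10000), seed = 77)
  peaks <- gr("chrU", c(1000, 3000, 5000, 7000, 8500),
              c(1099, 3099, 5099, 7099, 8599))
  fpos <- seq(300, 9700, length.out = 20)
  feats <- list(pts = gr("chrU", fpos, fpos))
  cfg <- analysis_config(n_permutations = 1000, gc_tolerance = 0.999)
  res <- enrichment_analysis(peaks, feats, g, cfg, window_bp = 50)
  perm <- attr(res, "perm_counts")["pts", ]
  ## a feature is hit when a peak start falls in a 200-position window
  ## out of the 9901 valid starts
  q <- 200 / (10000 - 100 + 1)
  expected <- 20 * (1 - (1 - q)^5)
  se <- sd(perm) / sqrt(length(perm))
  expect_lt(abs(mean(perm) - expected), 3 * se + 1e-9)
})

test_that("enrichment analysis flags planted classes and handles N=1", {
  spec <- small_spec(seed = 13)
  g <- make_genome(spec)
  f <- make_features(spec, g)
  p <- plant_peaks(spec, g, f)
  set.seed(14)
  res <- enrichment_analysis(p$pfh1, f, g,
                             analysis_config(n_permutations = 200))
  expect_s3_class(res, "enrichment_result")
  expect_equal(res$feature, names(f))
  expect_lte(res$p_value[res$feature == "trna"], 0.02)
  expect_true(all(res$p_value * 200 ==
                    round(res$p_value * 200)))

  set.seed(15)
  res1 <- enrichment_analysis(p$pfh1, f["trna"], g,
                              analysis_config(n_permutations = 1))
  expect_true(res1$p_value %in% c(0, 1))
  expect_equal(res1$below_resolution, res1$p_value == 0)
})
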