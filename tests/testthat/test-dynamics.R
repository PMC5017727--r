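test_that("condition matching merges regions and zero-imputes absences", {
  a <- gr("chrI", 1, 10, strength = 30)
  m <- match_conditions(a, a[0])
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$strength_a, m$strength_b), c(30, 0))

  b <- gr("chrI", 6, 15, strength = 50)
  m2 <- match_conditions(a, b)
  expect_equal(nrow(m2), 1L)
  expect_equal(c(m2$start, m2$end), c(1, 15))
  expect_equal(c(m2$strength_a, m2$strength_b), c(30, 50))

  m3 <- match_conditions(b, b)
  expect_equal(m3$strength_a, m3$strength_b)

  nos <- gr("chrI", 1, 10)
  expect_error(match_conditions(nos, b), "strength")
})

test_that("matching is symmetric up to swapping strength columns", {
  set.seed(19)
  a <- random_intervals(30); a$strength <- runif(30, 10, 200)
  b <- random_intervals(25); b$strength <- runif(25, 10, 200)
  ab <- match_conditions(a, b)
  ba <- match_conditions(b, a)
  expect_equal(ab$strength_a, ba$strength_b)
  expect_equal(ab$strength_b, ba$strength_a)
  expect_equal(ab[c("chrom", "start", "end")],
               ba[c("chrom", "start", "end")])
  ## per-region strength is the max over overlapping peaks
  reg <- GRanges(ab$chrom, IRanges::IRanges(ab$start, ab$end))
  for (i in seq_len(nrow(ab))) {
    ov <- a[bf_associated(a, reg[i], 0)]
    expect_equal(ab$strength_a[i],
                 if (length(ov) == 0) 0 else max(ov$strength))
  }
})

test_that("fraction stronger uses strict inequality with ties in the denominator", {
  m <- data.frame(strength_a = c(1, 2, 3), strength_b = c(2, 3, 1))
  expect_equal(fraction_stronger(m), 2 / 3)
  expect_equal(fraction_stronger(data.frame(strength_a = 1:3,
                                            strength_b = 1:3)), 0)
  expect_equal(fraction_stronger(data.frame(strength_a = 0,
                                            strength_b = 5)), 1)
  expect_error(fraction_stronger(m[0, ]), "no matched regions")
  ## complementarity: f(A,B) + f(B,A) <= 1, equality iff no ties
  set.seed(23)
  x <- data.frame(strength_a = sample(1:5, 40, TRUE),
                  strength_b = sample(1:5, 40, TRUE))
  swap <- data.frame(strength_a = x$strength_b, strength_b = x$strength_a)
  s <- fraction_stronger(x) + fraction_stronger(swap)
  expect_lte(s, 1)
  expect_equal(s == 1, !any(x$strength_a == x$strength_b))
})

test_that("signed-rank test agrees with exact enumeration for n <= 25", {
  ## symmetric differences give p = 1
  d <- c(3.5, -3.5, 7.2, -7.2, 1.1, -1.1)
  m <- data.frame(strength_a = 0, strength_b = d)
  expect_equal(wilcoxon_paired(m)$p, 1)

  ## all 20 pairs stronger in B: smallest attainable two-sided p
  set.seed(31)
  d20 <- runif(20, 1, 10)
  m20 <- data.frame(strength_a = 0, strength_b = d20)
  w <- wilcoxon_paired(m20)
  expect_equal(w$p, bf_signrank_p(d20), tolerance = 1e-12)
  expect_equal(w$p, 2 / 2^20, tolerance = 1e-12)

  ## random untied cases across sizes, against the DP oracle
  for (n in c(5, 12, 18, 25)) {
    for (rep in 1:3) {
      d <- round(rnorm(n, 0.3, 1), 6)
      d <- d[d != 0]
      if (any(duplicated(abs(d)))) next
      m <- data.frame(strength_a = 0, strength_b = d)
      expect_equal(wilcoxon_paired(m)$p, bf_signrank_p(d),
                   tolerance = 1e-12, label = paste("n =", n))
    }
  }

  ## zeros dropped; all-zero input refuses
  mz <- data.frame(strength_a = c(1, 2, 5), strength_b = c(1, 2, 9))
  expect_equal(wilcoxon_paired(mz)$n_used, 1L)
  expect_error(wilcoxon_paired(data.frame(strength_a = 1:3,
                                          strength_b = 1:3)),
               "all paired differences")

  ## a large planted shift is detected far below any printed precision
  set.seed(37)
  big <- data.frame(strength_a = rnorm(1000, 100, 5))
  big$strength_b <- big$strength_a + 10 + rnorm(1000, 0, 5)
  wb <- wilcoxon_paired(big)
  expect_lt(wb$p, 1e-10)
})

test_that("stratification keeps regions near the feature class", {
  m <- data.frame(chrom = "chrI", start = c(1, 500, 900),
                  end = c(100, 600, 950),
                  strength_a = c(1, 2, 3), strength_b = c(2, 1, 4))
  class(m) <- c("region_matches", "data.frame")
  f <- gr("chrI", c(90, 940), c(120, 960))
  expect_equal(nrow(stratify_by_feature(m, f[0], 0)), 0L)
  expect_equal(stratify_by_feature(m, f, 0)$start, c(1, 900))
  expect_equal(nrow(stratify_by_feature(m, f, 400)), 3L)
  ## brute-force agreement on random layouts
  set.seed(41)
  mm <- match_conditions(
    {a <- random_intervals(20); a$strength <- runif(20); a},
    {b <- random_intervals(20); b$strength <- runif(20); b})
  fr <- random_intervals(10)
  got <- stratify_by_feature(mm, fr, 15)
  reg <- GRanges(mm$chrom, IRanges::IRanges(mm$start, mm$end))
  expect_equal(got$start, mm$start[bf_associated(reg, fr, 15)])
})

test_that("venn counts partition both peak sets", {
  a <- gr("chrI", c(1, 100), c(10, 120))
  expect_equal(venn_counts(a, a),
               list(only_a = 0L, only_b = 0L, n_a_shared = 2L,
                    n_b_shared = 2L))
  b <- gr("chrII", c(1, 100), c(10, 120))
  expect_equal(venn_counts(a, b)$n_a_shared, 0L)
  set.seed(43)
  x <- random_intervals(30); y <- random_intervals(40)
  v <- venn_counts(x, y, 5)
  expect_equal(v$n_a_shared, sum(bf_associated(x, y, 5)))
  expect_equal(v$only_a + v$n_a_shared, length(x))
  expect_equal(v$only_b + v$n_b_shared, length(y))
})

test_that("fraction stronger rises monotonically with the planted shift", {
  ## equal peak counts and full sharing isolate the shift: every region
  ## is a matched pair, so delta = 0 is a per-region coin flip
  fs <- vapply(c(0, 5, 10, 20), function(delta) {
    spec <- small_spec(seed = 17, share_fraction = 1,
                       n_peaks = c(pfh1 = 60, cdc20_wt = 50,
                                   cdc20_dep = 50, gh2a_wt = 20,
                                   gh2a_dep = 20),
                       strength_shift = c(cdc20 = delta, gh2a = delta))
    g <- make_genome(spec)
    f <- make_features(spec, g)
    p <- plant_peaks(spec, g, f)
    m <- rbind(match_conditions(p$cdc20_wt, p$cdc20_dep),
               match_conditions(p$gh2a_wt, p$gh2a_dep))
    fraction_stronger(m)
  }, numeric(1))
  expect_true(all(diff(fs) > 0))
  expect_lt(abs(fs[1] - 0.5), 0.2)  # no shift: coin flip per region
})
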