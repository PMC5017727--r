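rec <- function(ids, len, b1, b2, score, c1 = 0, c2 = 0) {
  data.frame(protein_id = ids, length_aa = len, bait_1 = b1, bait_2 = b2,
             ctrl_1 = c1, ctrl_2 = c2, saint_score = score,
             stringsAsFactors = FALSE)
}

test_that("confidence filter is inclusive and monotone", {
  r <- rec(c("a", "b", "c"), 100, 5, 5, c(0.95, 0.80, 0.79))
  expect_equal(saint_filter(r, 0.80)$protein_id, c("a", "b"))
  expect_equal(nrow(saint_filter(r, 0)), 3L)
  expect_equal(saint_filter(r, 1)$protein_id, character(0))
  set.seed(67)
  rr <- rec(sprintf("p%02d", 1:40), 100, 1, 1, runif(40))
  kept <- vapply(seq(0, 1, by = 0.1), function(th)
    nrow(saint_filter(rr, th)), integer(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("NSAF normalizes length-scaled counts to sum one", {
  expect_equal(unname(nsaf(rec(c("a", "b"), c(100, 100), 5, 5, 1))),
               c(0.5, 0.5))
  v <- nsaf(rec(c("a", "b"), c(100, 200), c(5, 5), c(5, 5), 1))
  expect_equal(unname(v), c(2 / 3, 1 / 3))
  set.seed(71)
  r <- rec(sprintf("p%02d", 1:30), sample(50:900, 30),
           rpois(30, 20), rpois(30, 20), runif(30))
  expect_equal(sum(nsaf(r)), 1, tolerance = 1e-12)
  ## invariant to multiplying all counts by a constant
  r7 <- r; r7$bait_1 <- 7L * r$bait_1; r7$bait_2 <- 7L * r$bait_2
  expect_equal(nsaf(r7), nsaf(r), tolerance = 1e-12)
  z <- rec("a", 100, 0, 0, 1)
  expect_error(nsaf(z), "zero")
  bad <- rec("a", -5, 3, 3, 1)
  expect_error(nsaf(bad), "positive")
})

test_that("NSAF/PAX ratios flag and exclude missing abundances", {
  r <- rec(c("a", "b", "c"), 100, c(10, 8, 2), c(10, 8, 2), 0.9)
  v <- unname(nsaf(r))
  pax <- c(a = v[1], b = v[2] / 4)  # c absent
  np <- nsaf_pax(r, pax)
  expect_equal(np$nsaf_pax[1], 1)
  expect_equal(np$nsaf_pax[2], 4)
  expect_true(np$pax_missing[3])
  expect_true(is.na(np$nsaf_pax[3]))
  np0 <- nsaf_pax(r, c(a = 1, b = 1, c = 0))
  expect_true(np0$pax_missing[3])
})

test_that("phase classes follow the summed-count comparison", {
  s <- rec(c("a", "b", "c", "d", "e"), 100,
           c(5, 5, 3, 2, 0), c(5, 5, 2, 3, 0), 0.9)
  g2 <- rec(c("a", "b", "c", "d", "e"), 100,
            c(0, 2, 3, 9, 0), c(0, 2, 2, 9, 0), 0.9)
  pc <- phase_comparison(s, g2)
  expect_equal(pc$phase_class,
               c("S-limited", "S-enriched", "unchanged", "G2-enriched",
                 "unclassified"))
  expect_equal(pc$spc_s, c(10, 10, 5, 5, 0))
  ## a protein absent from the G2 table counts as zero G2 spectra
  pc2 <- phase_comparison(s[1:2, ], g2[2, ])
  expect_equal(pc2$phase_class, c("S-limited", "S-enriched"))
})

test_that("interaction table recovers planted interactors deterministically", {
  set.seed(73)
  n <- 100
  truth <- seq_len(n) <= 20
  r <- rec(sprintf("p%03d", 1:n), sample(100:800, n),
           ifelse(truth, 40L, 1L), ifelse(truth, 38L, 1L),
           score = ifelse(truth, 0.95, 0.05))
  pax <- setNames(rlnorm(n, log(50), 1), r$protein_id)
  tab <- interaction_table(r, pax)
  expect_equal(sort(tab$protein_id), sort(r$protein_id[truth]))
  expect_false(is.unsorted(rev(tab$nsaf_pax[!tab$pax_missing])))

  empty <- interaction_table(r[0, ], pax)
  expect_equal(nrow(empty), 0L)

  ## NSAF/PAX ordering is invariant under uniform count and PAX scaling
  r2 <- r; r2$bait_1 <- 3L * r$bait_1; r2$bait_2 <- 3L * r$bait_2
  tab2 <- interaction_table(r2, pax * 11)
  expect_equal(tab2$protein_id, tab$protein_id)

  ## edges restricted to retained proteins, no online lookup
  edges <- data.frame(protein_a = c("p001", "p001", "p099"),
                      protein_b = c("p002", "p050", "p100"))
  tab3 <- interaction_table(r, pax, known_edges = edges)
  expect_equal(nrow(attr(tab3, "edges")), 1L)
})
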