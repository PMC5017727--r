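---
title: "helipeak: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{helipeak: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific setting

Accessory replicative helicases such as the fission-yeast Pif1-family
helicase Pfh1 help replication forks move past hard-to-replicate sites:
tRNA and 5S rRNA genes, highly transcribed RNA polymerase II genes,
nucleosome-depleted regions (NDRs), G-quadruplex motifs, and other loci
bound by stable protein complexes. ChIP-seq of the helicase, of the
leading-strand DNA polymerase catalytic subunit (Cdc20/Pol2, whose high
occupancy marks fork slowing), and of phosphorylated H2A (γ-H2A, a
kilobase-scale DNA-damage mark), in wild-type and helicase-depleted
cells, yields peak sets whose joint analysis asks three questions:

1. Which annotated feature classes are helicase peaks associated with,
   beyond what peak length, chromosome, and GC composition alone
   predict?
2. Do fork-slowing and damage peaks grow stronger when the helicase is
   depleted, and at which feature classes?
3. Which proteins co-purify with the helicase, at what enrichment over
   their proteome abundance, and is the interaction S-phase dependent?

`helipeak` implements the full analysis layer for these questions, plus
a synthetic-data generator so every stage runs and is testable without
any external download.

## The permutation enrichment model

A feature is *associated* with a peak set when some peak lies within a
window `w` of it (edge-to-edge gap; overlap counts as distance zero).
The window is `peak_window_bp = 300` for protein-occupancy peaks — the
chromatin shearing size, so a peak cannot be localized more finely —
and `damage_window_bp = 5000` for γ-H2A, because damage-induced
phosphorylation spreads over roughly that scale around a break. A
feature associated with several peaks counts once; the statistic is the
number of associated features.

The null model scrambles the peak locations `n_permutations = 1000`
times while preserving, for every peak, its **length**, its
**chromosome**, and its **GC content**. GC matters because the helicase
binds preferentially to GC-rich sites, and many of the tested feature
classes are themselves GC-biased; an unmatched null would conflate
composition with biology. The empirical p-value is the fraction of
scrambled sets achieving at least the observed association count; when
no scrambled set does, the p-value is below the resolution of the test
and is reported as `< 1/N`, never as 0. One shared set of shuffles
scores all feature classes — statistically equivalent to independent
shuffles per class, cheaper, and reproducible from one seed.
Family-wise error is controlled by Bonferroni: with 16 classes at
α = 0.05 the threshold is 0.05/16 = 0.003125 (0.003 to one significant
figure).

Numerical choices in the shuffle:

* **GC tolerance.** Exact GC preservation is usually infeasible, so a
  shuffled window must match the original GC within
  `gc_tolerance = 0.02` (absolute fraction). If no window on the
  peak's chromosome qualifies, the tolerance doubles, at most five
  times, after which the peak is reported by name. Relaxation counts
  are returned per peak. In practice a peak's own window always
  qualifies, so the schedule only engages for degenerate inputs.
* **N bases** are excluded from both numerator and denominator of GC;
  all-N windows are never sampled.
* **Shuffled peaks may overlap** each other and their original
  location. Forbidding either would bias the null. The flip side,
  important at toy scales: the observed peaks of a real (or simulated)
  peak caller never overlap within one track, so if track coverage is
  high the shuffled sets cover systematically fewer distinct bases than
  the observed set and large classes drift toward small p-values. At
  realistic densities (a few percent of the genome) the effect is
  negligible; the package's recovery experiments therefore run at
  ~0.2 peaks/kb (see below).

The hypergeometric helper compares association *rates* between a
subset and its population (e.g., the 500 most highly expressed genes
against all RNA polymerase II genes) with an upper-tail test.

## Cross-condition peak strength

Peak strength is the MACS-style `-10·log10(p)` of the peak call. To
compare wild-type and depleted conditions the two peak sets are merged
into maximal disjoint regions; each region carries, per condition, the
maximum strength of that condition's overlapping peaks, or **0 when the
condition has no peak there**, so condition-specific peaks appear on an
axis of the strength scatter. Per-region maximum (rather than sum) is
insensitive to peak fragmentation.

Two summaries are reported. The *fraction stronger* is the fraction of
matched regions with strictly larger strength in the depleted
condition; ties stay in the denominator. It deliberately implements the
plotted quantity directly — no per-region significance call is made,
since none is well defined for a single region. The *Wilcoxon
signed-rank test* on the paired strengths drops zero differences (the
Wilcoxon convention), uses the exact distribution for n ≤ 25 untied
differences and the normal approximation with continuity correction
otherwise, and flags p-values below 1e-50 as "approximately zero", the
conventional reporting floor for genome-scale comparisons. Venn overlap
counts between two peak sets default to direct overlap (window 0);
which window genome-scale overlap figures use is rarely stated, so it
is configurable.

## Signal tracks

Per-base signal is `log2((IP + c) / (input + c))` with pseudocount
`c = 1` added to both channels, which maps zero/zero positions to
exactly 0. Smoothing convolves with a Hanning window
(`w_k = 0.5·(1 − cos(2πk/m))`) of length `hanning_bp + 1`, forced odd
so the output stays phase-aligned; weights are normalized to sum 1, and
near the track ends the truncated kernel is renormalized, so constants
are reproduced exactly and no spurious edge dips appear in 10 kb
gene-centered plots. Whether input counts are read starts or full
fragment coverage is up to the caller; both are accepted.

## IP-MS post-processing

Interaction-confidence scores (SAINT-style, in [0, 1]) are consumed as
input — the scoring algorithm itself is published, external, and out of
scope. The filter keeps scores `>= 0.80` (inclusive), a conventional
high-confidence cutoff. NSAF for protein *i* is
`(SpC_i / L_i) / Σ_j (SpC_j / L_j)` with spectral counts summed across
the two replicates before normalization; for equal-depth replicates
summing and averaging give identical NSAF, and summing is robust to a
zero-count replicate. NSAF is computed over **all detected proteins**
(so it reflects full sample complexity) before the confidence filter
subsets the table. Dividing by the proteome abundance (PAX) gives the
enrichment of each interactor relative to its cellular level; proteins
absent from the abundance table (or with zero abundance) are flagged
and excluded from the ratio rather than imputed. Phase dependence is
the descriptive comparison of summed S and G2 counts — S-limited
(absent in G2), S-enriched, unchanged, or G2-enriched — mirroring how
such comparisons are reported; no test is attached to them.

## The synthetic-data generator

The generator emulates the statistical structure of deposited
ChIP-seq peak tables and IP-MS count tables, not their biology:

* **Genome**: 3 chromosomes × 200 kb, i.i.d. bases within 10 kb blocks
  whose GC targets are uniform on [0.30, 0.50] (around the fission
  yeast genome's ~0.36). The desk scale keeps a 1000-permutation
  enrichment run under half a minute.
* **Features**: sixteen classes with counts and lengths scaled from a
  real annotation set (tRNA-like 40 × 80 bp, 5S-like 12 × 120 bp,
  genes ~1.4 kb, UTRs, promoters, NDRs, origins, DSB hotspots, G4-like
  motifs, ...), placed uniformly.
* **Peaks**: placed with probability proportional to a per-class
  enrichment weight over the class footprint (features ± 300 bp),
  uniform elsewhere, never overlapping within one track. The default
  per-condition counts are the deposited peak-set sizes of the
  motivating study: 621 helicase, 485/517 polymerase-occupancy
  (wild-type/depleted), 179/582 damage-mark peaks.
* **Condition pairs**: 80% of wild-type peaks are re-used verbatim in
  the depleted condition (giving shared counts of 388 and 143);
  depleted-specific peaks avoid the wild-type track entirely, since a
  depleted-specific site is by definition one without a wild-type
  peak. Re-used peaks receive a strength shift δ plus `N(0, √2·σ)`
  pairing noise with σ = 5, so the probability that a shared region is
  stronger after depletion is `q = Φ(δ/(√2σ))`. The default shifts are
  derived by inverting the reported headline fractions: with `n_wt`,
  `n_dep`, and `n_share` regions, the expected overall
  fraction-stronger is `(n_dep − n_share + n_share·q) / n_regions`;
  solving for the reported 64% (polymerase) gives q = 0.680, δ = 3.3,
  and for 88% (damage mark) q = 0.733, δ = 4.4. Strengths themselves
  come from a binomial-tail model (`IP ~ Pois(4·50)` vs
  `input ~ Pois(50)`, strength = −10·log10 of the upper binomial
  tail), so they live on the MACS scale (~150–300).
* **Coverage**: input `Pois(depth)`, IP `Pois(depth·fold)` inside
  peaks, defaults depth 100, fold 4.
* **Spectral counts**: 100 proteins, 20 true interactors with bait
  counts `Pois(30)` per replicate versus background `Pois(2)`, scores
  `Beta(20, 1.5)` for true and `Beta(1.5, 20)` for false interactors
  (so the 0.80 cutoff recovers ≥ 90% of true interactors at ≤ 10%
  false discovery by construction), G2 bait means scaled by a
  depletion factor of 0.4, and a proteome-abundance table missing 5%
  of proteins to exercise the exclusion path.

Everything is deterministic given the master seed; each generator uses
a fixed offset from it, so stages can be regenerated independently.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: read-level noise and mappability, fragment
size distributions, peak-caller artifacts, GC-biased placement of
features (feature GC here matches the genome background, so the
GC-matching of the null is exercised by property tests rather than by a
planted confounder), correlated annotation structure (real UTRs flank
real genes), and kilobase-scale damage domains (desk-scale damage peaks
are ~300 bp).

## Problem sizes of the shipped experiments

Two experiment scales are used deliberately:

* The *emulation bundle* (default spec) keeps the study's absolute peak
  counts, which the count, Venn-overlap, and fraction-stronger
  statistics need. Its track coverage (~30% of the desk genome) is far
  above realistic density, which is harmless for those statistics but,
  per the null-model note above, would bias the permutation test.
* The *recovery experiments* (planted-enrichment and shift recovery)
  instead use 120 helicase peaks (~0.2/kb, within a factor of four of
  the deposited data's 0.05/kb) and a single weighted class
  (tRNA-like, weight 20). There the planted class reaches the
  permutation floor (`< 0.001` at 1000 permutations) while unweighted
  classes stay non-significant, and a planted +10 strength shift on
  fully shared peak sets makes > 90% of matched regions stronger
  (q = Φ(10/√50) = 0.92). The shift-recovery experiment equalizes the
  per-condition peak counts so that every region is a matched pair and
  δ = 0 reduces to a per-region coin flip.

## Known limitations

* The per-peak "stronger" call is a raw strict inequality; analyses
  that define per-peak significance statistically may print slightly
  different percentages on the same data.
* The shuffle preserves GC marginally per peak; it does not preserve
  joint spatial structure (e.g. clustering of peaks), which is the
  standard trade-off of positional permutation nulls.
* At toy genome scales the 5 kb damage-association window saturates
  (everything is within 5 kb of everything); genome-scale inputs are
  required for that window to discriminate.
* Spectral-count phase classes are descriptive; with one pair of
  pooled counts per protein no error rate is attached.
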