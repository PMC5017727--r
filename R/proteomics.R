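## IP-MS spectral-count post-processing: confidence-score filtering,
## NSAF (normalized spectral abundance factor), NSAF relative to
## proteome abundance (PAX), and S-versus-G2 phase-dependence calls.
## Spectral counts are summed across replicates before NSAF; for
## equal-depth replicates this matches per-replicate averaging after
## normalization and is robust to a zero-count replicate.

.bait_cols <- function(records) grep("^bait_", names(records), value = TRUE)

.total_counts <- function(records) {
  cols <- .bait_cols(records)
  if (length(cols) == 0L) stop("no bait_* columns in records")
  rowSums(records[, cols, drop = FALSE])
}

#' Filter records by interaction-confidence score
#'
#' Retains records with `saint_score >= threshold` (inclusive, so a
#' threshold of 0.80 keeps a score of exactly 0.80).
#'
#' @param records Spectral-count `data.frame` (see
#'   [read_spectral_counts()]).
#' @param threshold Cutoff in \[0, 1\].
#' @return Subset of `records`.
#' @export
saint_filter <- function(records, threshold = 0.80) {
  stopifnot(threshold >= 0, threshold <= 1)
  records[records$saint_score >= threshold, , drop = FALSE]
}

#' Normalized spectral abundance factor (NSAF)
#'
#' `NSAF_i = (SpC_i / L_i) / sum_j (SpC_j / L_j)`, with spectral counts
#' summed over bait replicates and L the protein length in amino acids.
#' Values sum to 1 over the records supplied, so NSAF is relative to the
#' complexity of that sample.
#'
#' @param records Spectral-count `data.frame` with `length_aa` and
#'   `bait_*` columns.
#' @return Named numeric vector of NSAF values (names = protein ids).
#' @export
nsaf <- function(records) {
  if (nrow(records) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (any(records$length_aa <= 0)) stop("protein length must be positive")
  spc <- .total_counts(records)
  if (sum(spc) == 0) stop("total bait spectral counts are zero")
  saf <- spc / records$length_aa
  stats::setNames(saf / sum(saf), records$protein_id)
}

#' NSAF relative to proteome abundance (NSAF/PAX)
#'
#' Divides each protein's NSAF by its whole-proteome abundance, giving
#' the enrichment of the protein in the isolation relative to its
#' cellular abundance. Proteins missing from the abundance table, or
#' with zero abundance, are flagged and excluded from the ratio.
#'
#' @param records Spectral-count `data.frame`.
#' @param pax Named numeric vector of proteome abundances.
#' @return `data.frame` with `protein_id`, `nsaf`, `pax`, `nsaf_pax`,
#'   and `pax_missing` (logical; `nsaf_pax` is `NA` for those rows).
#' @export
nsaf_pax <- function(records, pax) {
  v <- nsaf(records)
  pax_val <- unname(pax[records$protein_id])
  missing <- is.na(pax_val) | pax_val <= 0
  ratio <- ifelse(missing, NA_real_, unname(v) / pax_val)
  data.frame(protein_id = records$protein_id,
             nsaf = unname(v),
             pax = pax_val,
             nsaf_pax = ratio,
             pax_missing = missing,
             stringsAsFactors = FALSE)
}

#' Classify S-versus-G2 phase dependence of interactions
#'
#' Descriptive comparison of summed bait spectral counts between S and
#' G2 phase isolations (no statistical test): `S-limited` when a protein
#' is detected in S but not at all in G2, `S-enriched` when detected in
#' both but lower in G2, `unchanged` when equal, `G2-enriched` when
#' higher in G2, and `unclassified` when undetected in S.
#'
#' @param records_s,records_g2 Spectral-count `data.frame`s sharing a
#'   protein-id space.
#' @return `data.frame` with `protein_id`, `spc_s`, `spc_g2`,
#'   `phase_class`.
#' @export
phase_comparison <- function(records_s, records_g2) {
  s <- stats::setNames(.total_counts(records_s), records_s$protein_id)
  g2 <- stats::setNames(.total_counts(records_g2), records_g2$protein_id)
  ids <- records_s$protein_id
  g2v <- ifelse(ids %in% names(g2), g2[ids], 0)
  cls <- ifelse(s[ids] == 0, "unclassified",
                ifelse(g2v == 0, "S-limited",
                       ifelse(g2v < s[ids], "S-enriched",
                              ifelse(g2v == s[ids], "unchanged",
                                     "G2-enriched"))))
  data.frame(protein_id = ids,
             spc_s = unname(s[ids]),
             spc_g2 = unname(g2v),
             phase_class = unname(cls),
             stringsAsFactors = FALSE)
}

#' High-confidence interactor table
#'
#' Applies the confidence-score filter, computes NSAF over all detected
#' proteins (so the normalization reflects full sample complexity)
#' before subsetting, attaches NSAF/PAX enrichment and, when G2 records
#' are given, phase-dependence calls. Rows are sorted by decreasing
#' NSAF/PAX (missing-abundance proteins last). Network edges are taken
#' only from a user-supplied known-interaction table; no online lookup.
#'
#' @param records S-phase spectral-count `data.frame`.
#' @param pax Named proteome-abundance vector.
#' @param config An [analysis_config()] (supplies `saint_threshold`).
#' @param records_g2 Optional G2-phase records for phase classification.
#' @param known_edges Optional `data.frame` with columns `protein_a`,
#'   `protein_b` of known interactions; edges between retained proteins
#'   are returned in the `edges` attribute.
#' @return `data.frame` of retained interactors with columns
#'   `protein_id`, `saint_score`, `spc`, `nsaf`, `pax`, `nsaf_pax`,
#'   `pax_missing` and (with G2 data) `phase_class`.
#' @export
interaction_table <- function(records, pax, config = analysis_config(),
                              records_g2 = NULL, known_edges = NULL) {
  if (nrow(records) == 0L) {
    out <- data.frame(protein_id = character(0), saint_score = numeric(0),
                      spc = numeric(0), nsaf = numeric(0),
                      pax = numeric(0), nsaf_pax = numeric(0),
                      pax_missing = logical(0))
    attr(out, "edges") <- NULL
    return(out)
  }
  np <- nsaf_pax(records, pax)
  keep <- records$saint_score >= config$saint_threshold
  out <- data.frame(protein_id = records$protein_id[keep],
                    saint_score = records$saint_score[keep],
                    spc = .total_counts(records)[keep],
                    nsaf = np$nsaf[keep],
                    pax = np$pax[keep],
                    nsaf_pax = np$nsaf_pax[keep],
                    pax_missing = np$pax_missing[keep],
                    stringsAsFactors = FALSE)
  if (!is.null(records_g2)) {
    pc <- phase_comparison(records, records_g2)
    out$phase_class <- pc$phase_class[match(out$protein_id,
                                            pc$protein_id)]
  }
  out <- out[order(out$pax_missing, -ifelse(is.na(out$nsaf_pax), -Inf,
                                            out$nsaf_pax)), ,
             drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(known_edges)) {
    e <- known_edges[known_edges$protein_a %in% out$protein_id &
                       known_edges$protein_b %in% out$protein_id, ,
                     drop = FALSE]
    attr(out, "edges") <- e
  }
  out
}
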