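## Readers and writers for the external formats the pipeline touches:
## FASTA genomes, BED (3-6 column) and GFF3 annotations, and TSV tables
## (peaks with strengths, spectral counts, proteome abundances). All
## plain-text coordinates are BED-style 0-based half-open; internal
## GRanges are 1-based closed, converted at this boundary.

#' Read a genome from FASTA
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet], one entry per chromosome, bases
#'   upper-cased; names are the first whitespace-delimited token of each
#'   header.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  genome <- tryCatch(Biostrings::readDNAStringSet(path),
                     error = function(e)
                       stop("malformed FASTA '", path, "': ",
                            conditionMessage(e), call. = FALSE))
  if (length(genome) == 0L) stop("empty FASTA: ", path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome)))
    stop("duplicate chromosome names in ", path)
  Biostrings::DNAStringSet(toupper(genome))
}

#' Write a genome to FASTA
#'
#' @param genome A `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read intervals from BED or GFF3
#'
#' BED input is 0-based half-open and read as-is; GFF3 (1-based closed) is
#' converted on read, so both arrive on identical internal coordinates.
#' A numeric BED score / GFF3 score column is exposed as the `strength`
#' metadata column.
#'
#' @param path Input file.
#' @param format `"bed"` or `"gff3"`.
#' @return `GRanges` with optional `strength` column.
#' @export
read_intervals <- function(path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = format),
                 error = function(e)
                   stop("cannot parse ", format, " file '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  gr <- methods::as(gr, "GRanges")
  mc <- S4Vectors::mcols(gr)
  if ("score" %in% colnames(mc)) {
    S4Vectors::mcols(gr)$strength <- as.numeric(mc$score)
  }
  if (any(GenomicRanges::width(gr) < 1L))
    stop("file '", path, "': interval with start >= end after conversion")
  gr
}

#' Write intervals as BED
#'
#' Coordinates are converted to 0-based half-open; a `strength` column is
#' written as the BED score.
#'
#' @param gr `GRanges`.
#' @param path Output path (should end in `.bed`).
#' @return `path`, invisibly.
#' @export
write_intervals_bed <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  strength <- S4Vectors::mcols(gr)$strength
  if (!is.null(strength)) {
    df$name <- if (!is.null(S4Vectors::mcols(gr)$label))
      S4Vectors::mcols(gr)$label else "."
    df$score <- strength
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a peak table (TSV with header)
#'
#' Expected columns: `chrom`, `start`, `end` (0-based half-open), and
#' optionally `strength` (-10*log10 p, MACS convention). Unknown columns
#' are preserved as metadata columns. Strength-dependent stages refuse
#' missing strengths rather than imputing.
#'
#' @param path TSV file with a header row.
#' @param condition Condition label attached as
#'   `S4Vectors::metadata(x)$condition`.
#' @return `GRanges` with `strength` column when present.
#' @export
read_peak_table <- function(path, condition) {
  stopifnot(is.character(condition), nzchar(condition))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "start", "end")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stop("peak table '", path, "' lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- which(!(df$start < df$end))
  if (length(bad) > 0L)
    stop("peak table '", path, "': start >= end on line(s) ",
         paste(utils::head(bad + 1L, 5L), collapse = ", "),
         " (line 1 is the header)")
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  extra <- setdiff(names(df), need)
  for (nm in extra) S4Vectors::mcols(gr)[[nm]] <- df[[nm]]
  if ("strength" %in% extra && any(gr$strength < 0, na.rm = TRUE))
    stop("peak table '", path, "': negative strength")
  S4Vectors::metadata(gr)$condition <- condition
  gr
}

#' Write a peak table (TSV, 0-based half-open)
#'
#' @param peaks `GRanges`, optionally with `strength`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(peaks)),
                   start = GenomicRanges::start(peaks) - 1L,
                   end = GenomicRanges::end(peaks))
  mc <- S4Vectors::mcols(peaks)
  for (nm in colnames(mc)) df[[nm]] <- mc[[nm]]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read IP-MS spectral-count records
#'
#' Expected columns: `protein_id`, `length_aa`, at least one `bait_*`
#' replicate column, `ctrl_*` replicate columns, and `saint_score`.
#' Unknown columns are preserved.
#'
#' @param path TSV file with header.
#' @return `data.frame` of protein records.
#' @export
read_spectral_counts <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("protein_id", "length_aa", "saint_score")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stop("spectral-count table '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!any(grepl("^bait_", names(df))))
    stop("spectral-count table '", path, "' has no bait_* column")
  cnt <- grep("^(bait|ctrl)_", names(df), value = TRUE)
  for (nm in cnt) {
    if (any(df[[nm]] < 0) || any(df[[nm]] != round(df[[nm]])))
      stop("spectral-count table '", path, "': column ", nm,
           " must hold nonnegative integer counts")
  }
  if (any(df$length_aa <= 0))
    stop("spectral-count table '", path, "': length_aa must be positive")
  if (any(df$saint_score < 0 | df$saint_score > 1))
    stop("spectral-count table '", path, "': saint_score outside [0, 1]")
  df
}

#' Read a proteome-abundance (PAX) table
#'
#' @param path TSV with header columns `protein_id` and `pax`.
#' @return Named numeric vector of abundances.
#' @export
read_pax_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("protein_id", "pax"), names(df))
  if (length(missing_cols) > 0L)
    stop("PAX table '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  stats::setNames(as.numeric(df$pax), df$protein_id)
}

#' Write a result table as TSV
#'
#' @param table `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
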