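## End-to-end orchestration over a synthetic fixture bundle:
## simulate -> enrich -> compare -> signal -> ipms, with a JSON run
## manifest recording the configuration, seed, input digests, and
## per-stage outputs so a rerun with the same manifest inputs is
## byte-identical for the deterministic stages.

#' Run the full pipeline on a synthetic bundle
#'
#' Executes, in order: data simulation ([simulate_bundle()]), permutation
#' enrichment of the helicase peak set against every feature class
#' ([enrichment_analysis()]), wild-type versus depleted comparisons for
#' the polymerase-occupancy and damage-mark tracks
#' ([compare_conditions()]), a smoothed log2(IP/input) signal slice
#' around the first tRNA-class feature ([log2_ratio()],
#' [hanning_smooth()], [extract_region()]), and IP-MS post-processing
#' ([interaction_table()]). Five result tables plus a manifest are
#' written under `out_dir`.
#'
#' @param config An [analysis_config()]; `config$seed` (if set) seeds the
#'   simulation spec unless `spec` is supplied.
#' @param spec A [simulation_spec()]; defaults to
#'   `simulation_spec(seed = config$seed)`.
#' @param out_dir Output directory.
#' @return List of class `"pipeline_run"` with elements `bundle`,
#'   `enrichment`, `comparison_cdc20`, `comparison_gh2a`, `signal`,
#'   `ipms`, `manifest`.
#' @export
run_all <- function(config = analysis_config(seed = 1),
                    spec = NULL, out_dir = tempfile("helipeak_run_")) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(spec))
    spec <- simulation_spec(seed = if (is.null(config$seed)) 1 else
      config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  bundle <- stage("simulate", simulate_bundle(spec, file.path(out_dir,
                                                              "inputs")))

  enr <- stage("enrich", {
    if (!is.null(spec$seed)) set.seed(spec$seed + 10L)
    enrichment_analysis(bundle$peaks$pfh1, bundle$features,
                        bundle$genome, config)
  })
  write_results(as.data.frame(enr), file.path(out_dir, "enrichment.tsv"))

  strata_classes <- bundle$features[intersect(c("trna", "rrna_5s", "ndr",
                                                "top_expressed"),
                                              names(bundle$features))]
  cmp_cdc20 <- stage("compare",
    compare_conditions(bundle$peaks$cdc20_wt, bundle$peaks$cdc20_dep,
                       strata_classes, config$peak_window_bp))
  cmp_gh2a <- stage("compare",
    compare_conditions(bundle$peaks$gh2a_wt, bundle$peaks$gh2a_dep,
                       strata_classes, config$damage_window_bp))
  write_results(rbind(cbind(track = "cdc20", rbind(cmp_cdc20$overall,
                                                   cmp_cdc20$strata)),
                      cbind(track = "gh2a", rbind(cmp_gh2a$overall,
                                                  cmp_gh2a$strata))),
                file.path(out_dir, "comparison.tsv"))

  sig <- stage("signal", {
    ch1 <- names(bundle$genome)[1]
    raw <- log2_ratio(bundle$coverage$ip[[ch1]],
                      bundle$coverage$input[[ch1]],
                      pseudocount = config$pseudocount, chrom = ch1)
    sm <- hanning_smooth(raw, config$hanning_bp)
    tr <- bundle$features$trna
    tr1 <- tr[as.character(GenomicRanges::seqnames(tr)) == ch1]
    center <- if (length(tr1) > 0) {
      mid <- (GenomicRanges::start(tr1) + GenomicRanges::end(tr1)) %/% 2L
      mid[which.min(abs(mid - Biostrings::width(bundle$genome)[1] %/% 2L))]
    } else Biostrings::width(bundle$genome)[1] %/% 2L
    half <- 5000L
    center <- min(max(center, half + 1L),
                  Biostrings::width(bundle$genome)[1] - half)
    extract_region(sm, center, half)
  })
  write_results(data.frame(chrom = sig$chrom,
                           pos = seq_along(sig$values) + sig$start - 2L,
                           smoothed_log2_ratio = sig$values),
                file.path(out_dir, "signal_region.tsv"))

  ipms <- stage("ipms",
    interaction_table(bundle$spectral$s, bundle$spectral$pax, config,
                      records_g2 = bundle$spectral$g2))
  write_results(ipms, file.path(out_dir, "interactors.tsv"))

  venn_df <- data.frame(track = c("cdc20", "gh2a"),
                        only_wt = c(cmp_cdc20$venn$only_a,
                                    cmp_gh2a$venn$only_a),
                        shared_wt = c(cmp_cdc20$venn$n_a_shared,
                                      cmp_gh2a$venn$n_a_shared),
                        shared_dep = c(cmp_cdc20$venn$n_b_shared,
                                       cmp_gh2a$venn$n_b_shared),
                        only_dep = c(cmp_cdc20$venn$only_b,
                                     cmp_gh2a$venn$only_b))
  write_results(venn_df, file.path(out_dir, "venn.tsv"))

  manifest <- list(
    tool = "helipeak",
    version = as.character(utils::packageVersion("helipeak")),
    seed = spec$seed,
    config = config[setdiff(names(config), "seed")],
    spec = list(n_chromosomes = spec$n_chromosomes,
                chromosome_length_bp = spec$chromosome_length_bp,
                n_peaks = as.list(spec$n_peaks),
                share_fraction = spec$share_fraction,
                strength_shift = as.list(spec$strength_shift),
                enrichment = as.list(spec$enrichment)),
    input_digests = as.list(tools::md5sum(unlist(bundle$paths))),
    outputs = file.path(out_dir,
                        c("enrichment.tsv", "comparison.tsv",
                          "signal_region.tsv", "interactors.tsv",
                          "venn.tsv")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  structure(list(bundle = bundle, enrichment = enr,
                 comparison_cdc20 = cmp_cdc20,
                 comparison_gh2a = cmp_gh2a,
                 signal = sig, ipms = ipms, manifest = manifest,
                 out_dir = out_dir),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline run ->", x$out_dir, "\n")
  cat(sprintf("  %d feature classes tested, %d significant\n",
              nrow(x$enrichment), sum(x$enrichment$significant)))
  cat(sprintf("  cdc20: %.0f%% stronger after depletion; gh2a: %.0f%%\n",
              100 * x$comparison_cdc20$overall$fraction_stronger_b,
              100 * x$comparison_gh2a$overall$fraction_stronger_b))
  cat(sprintf("  %d high-confidence interactors\n", nrow(x$ipms)))
  invisible(x)
}
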