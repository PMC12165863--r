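#' Run the full synthetic pipeline and write reports
#'
#' End-to-end driver used by the command-line interface: simulates alleles,
#' reads, a fragment trace and off-target pileups under one seed, runs every
#' analysis stage, and writes a per-read TSV, a JSON editing summary, an
#' instability TSV and an off-target TSV into `out_dir`. Identical inputs
#' and an identical seed produce byte-identical reports.
#'
#' @param config a [run_config()]; `config$seed` drives all randomness.
#' @param out_dir output directory (created if needed); defaults to
#'   `config$out_dir`.
#' @param n_reads number of simulated reads.
#' @param allele_model_args named list overriding [allele_model()] defaults.
#' @param trace_model_args named list overriding [trace_model()] defaults.
#' @return Invisibly, a named list of the paths written (`read_calls`,
#'   `summary`, `instability`, `offtarget`) plus the in-memory `summary`,
#'   `estimate`, `instability` and `offtarget` results.
#' @export
run_pipeline <- function(config = run_config(), out_dir = config$out_dir,
                         n_reads = 2000L,
                         allele_model_args = list(),
                         trace_model_args = list(expansion_fraction = 0.3,
                                                 expansion_shift = 6)) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- switch(config$spec,
                 "cag-cbe" = cag_cbe_spec(),
                 "gaa-abe" = gaa_abe_spec(),
                 stop("unknown spec reference: ", config$spec, call. = FALSE))
  seed <- config$seed

  amod <- do.call(allele_model, allele_model_args)
  alleles <- simulate_alleles(n_reads, amod, spec, seed = seed)
  reads <- simulate_reads(alleles, spec, read_length = 150L, seed = seed + 1L)
  calls <- call_reads(reads, spec)
  summ <- summarize_editing(calls, spec)
  est <- editing_estimate(summ, N = 3L * amod$modal_length)

  tmod <- do.call(trace_model, trace_model_args)
  trace <- simulate_trace(tmod, seed = seed + 2L, label = config$locus)
  instab <- instability_report(list(trace), tmod$reference_modal,
                               threshold = config$peak_height_fraction,
                               cap = config$contraction_cap)

  truth <- data.frame(locus = "OT1", pos = 1:3, ref = "C", alt = "T",
                      freq = c(0.1, 0.2, 0), background = c(FALSE, FALSE, TRUE))
  piles <- simulate_pileups(truth, coverage = 2000L, seed = seed + 3L)
  ot <- locus_editing(piles$treated$OT1, piles$untreated$OT1,
                      min_coverage = config$min_coverage,
                      detection_threshold = config$detection_threshold,
                      substantial_threshold = config$substantial_threshold,
                      locus = "OT1")
  ot_df <- data.frame(locus = ot$locus, status = ot$status,
                      evaluable_positions = ot$evaluable_positions,
                      probability = ot$probability,
                      untreated_probability = ot$untreated_probability)

  paths <- list(
    read_calls = file.path(out_dir, "read_calls.tsv"),
    summary = file.path(out_dir, "editing_summary.json"),
    instability = file.path(out_dir, "instability.tsv"),
    offtarget = file.path(out_dir, "offtarget.tsv")
  )
  write_report(calls, paths$read_calls, seed = seed, config = config)
  write_editing_summary(summ, paths$summary)
  write_report(instab, paths$instability, seed = seed, config = config)
  write_report(ot_df, paths$offtarget, seed = seed, config = config)

  invisible(c(paths, list(summary = summ, estimate = est,
                          instability = instab, offtarget = ot)))
}
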