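#' Run the estimation pipeline on files
#'
#' File-level orchestration: parse a BLAST tabular file, fit the abundance
#' estimate with [taec()] against a stored similarity matrix, and write the
#' abundance report. Stage progress (genome counts after elimination and
#' correction) is logged to stderr unless `quiet = TRUE`.
#'
#' @param hits_path BLAST tabular (outfmt 6) alignment file.
#' @param similarity_path similarity-matrix TSV
#'   (see [write_similarity_matrix()]).
#' @param out_path output path for the abundance report TSV.
#' @param control a [taec_control()].
#' @param quiet suppress stderr logging.
#' @return The fitted [taec()] object, invisibly.
#' @export
run_estimate <- function(hits_path, similarity_path, out_path,
                         control = taec_control(), quiet = FALSE) {
  log_msg <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  hits <- parse_blast_tabular(hits_path)
  log_msg("parsed %d hits (%d reads, %d genomes) from %s", nrow(hits),
          length(attr(hits, "read_ids")), length(attr(hits, "genome_ids")), hits_path)
  W <- read_similarity_matrix(similarity_path)
  fit <- taec(hits, W, control = control)
  log_msg("elimination: %d of %d genomes retained; correction: %d with positive counts",
          length(fit$retained_ids), fit$n_genomes_input,
          sum(!fit$estimates$dropped_in_correction))
  write_abundance_table(fit$estimates, out_path)
  log_msg("report written to %s (%.1f s elapsed)", out_path,
          as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(fit)
}

#' Evaluate an abundance report against a truth table
#'
#' @param estimated_path abundance report TSV (genome_id,
#'   corrected_read_count, relative_abundance).
#' @param truth_path truth TSV (genome_id, true_count).
#' @return An `error_report`, see [error_measures()].
#' @export
evaluate_files <- function(estimated_path, truth_path) {
  est <- utils::read.delim(estimated_path, stringsAsFactors = FALSE)
  tru <- utils::read.delim(truth_path, stringsAsFactors = FALSE)
  error_measures(stats::setNames(est$corrected_read_count, est$genome_id),
                 stats::setNames(tru$true_count, tru$genome_id))
}
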