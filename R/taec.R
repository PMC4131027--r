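#' Pipeline control parameters
#'
#' Collects the tunable parameters of the estimator with their standard
#' defaults: `alpha = 0.96` (the alpha-threshold for multi-assignment, chosen
#' as the value minimizing mean and variance of RRMSE on calibration
#' simulations), `k0 = 30000` simulated reads per genome for similarity
#' estimation, `similarity_threshold = 0.001` (similarities below 0.1% are
#' zeroed), `cutoff_frac = 0.0005` (bootstrap abundance cutoff of 0.05% of the
#' most abundant genome), `occurrence_frac = 0.05` (a genome below cutoff in
#' more than 5% of replicates is removed), `n_bootstraps = 100`, and
#' `min_reads = 1` (the relaxed elimination stopping criterion `c`).
#'
#' @param alpha alpha-threshold in `[0, 1]`.
#' @param k0 simulated reads per genome for similarity estimation.
#' @param similarity_threshold similarity floor.
#' @param cutoff_frac bootstrap abundance cutoff fraction in `(0, 1)`.
#' @param occurrence_frac bootstrap occurrence fraction in `[0, 1)`.
#' @param n_bootstraps number of bootstrap replicates; `0` disables the
#'   bootstrap filter and uses a single elimination pass with `c = min_reads`.
#' @param min_reads minimum claimed reads (`c`) for the non-bootstrap path.
#' @param seed integer seed governing the bootstrap resampling.
#' @return A list of class `taec_control`.
#' @export
taec_control <- function(alpha = 0.96, k0 = 30000L, similarity_threshold = 0.001,
                         cutoff_frac = 0.0005, occurrence_frac = 0.05,
                         n_bootstraps = 100L, min_reads = 1L, seed = 1L) {
  stopifnot(alpha >= 0, alpha <= 1, k0 >= 1,
            similarity_threshold >= 0, similarity_threshold < 1,
            cutoff_frac > 0, cutoff_frac < 1,
            occurrence_frac >= 0, occurrence_frac < 1,
            n_bootstraps >= 0, min_reads >= 1)
  structure(list(alpha = alpha, k0 = as.integer(k0),
                 similarity_threshold = similarity_threshold,
                 cutoff_frac = cutoff_frac, occurrence_frac = occurrence_frac,
                 n_bootstraps = as.integer(n_bootstraps),
                 min_reads = as.integer(min_reads), seed = as.integer(seed)),
            class = "taec_control")
}

#' Estimate genome relative abundances by elimination and correction
#'
#' The main fitting function. From an alignment hit table and a genome
#' similarity matrix it (1) builds the binary top-score assignment matrix,
#' (2) removes genomes without robust uniquely attributable reads by greedy
#' elimination under bootstrap resampling of the reads, (3) recounts reads
#' over the retained genomes with the alpha-threshold rule, and (4) corrects
#' those counts by solving the similarity linear system `W^T t = b`, dropping
#' genomes whose corrected count is non-positive.
#'
#' By default the alpha used for recounting is the one the similarity matrix
#' was built with, keeping counts and similarities consistent; overriding it
#' triggers a warning.
#'
#' @param hits a [hit_table()] (e.g. from [parse_blast_tabular()] or
#'   [naive_align()]).
#' @param similarity a [similarity_matrix()] covering (at least) the genomes
#'   that survive elimination.
#' @param control a [taec_control()] list of parameters.
#' @param alpha optional override of the alpha-threshold; defaults to the
#'   similarity matrix's own alpha.
#' @return An object of class `taec`; see [print.taec()], [summary.taec()],
#'   [coef.taec()], [fitted.taec()], [residuals.taec()], [plot.taec()].
#'   Components include `estimates` (the `abundance_estimate` data frame),
#'   `b` (alpha-threshold counts), `W` (restricted similarity matrix),
#'   `elimination` (bootstrap decisions), `retained_ids`, `eliminated_ids`,
#'   `control` and `n_reads`.
#' @examples
#' g <- c(generate_genome(2000, seed = 1, id = "gA"),
#'        generate_genome(2000, seed = 2, id = "gB"))
#' com <- synthetic_community(g, c(0.75, 0.25), 400, read_length = 80, seed = 3)
#' hits <- naive_align(simulate_reads(com), g)
#' W <- estimate_similarity(g, read_length = 80, K0 = 200, seed = 4)
#' fit <- taec(hits, W, control = taec_control(n_bootstraps = 20))
#' fit
#' @export
taec <- function(hits, similarity, control = taec_control(), alpha = NULL) {
  stopifnot(inherits(hits, "hit_table"), inherits(similarity, "similarity_matrix"),
            inherits(control, "taec_control"))
  if (is.null(alpha)) {
    alpha <- similarity$alpha
  } else if (abs(alpha - similarity$alpha) > 1e-12) {
    warning("alpha (", alpha, ") differs from the similarity matrix's alpha (",
            similarity$alpha, "); counts and similarities are no longer consistent")
  }
  if (nrow(hits) == 0L) stop("no assignable reads: hit table is empty")

  A <- top_score_matrix(hits)
  if (control$n_bootstraps > 0L) {
    el <- bootstrap_eliminate(A, n_bootstraps = control$n_bootstraps,
                              cutoff_frac = control$cutoff_frac,
                              occurrence_frac = control$occurrence_frac,
                              seed = control$seed)
    retained <- el$retained_ids
    decisions <- el$decisions
  } else {
    res <- eliminate_iterative(A, c = control$min_reads)
    retained <- res$retained_ids
    decisions <- data.frame(genome_id = colnames(A),
                            n_bootstraps = 0L, n_below_cutoff = NA_integer_,
                            eliminated = !(colnames(A) %in% retained),
                            stringsAsFactors = FALSE)
  }
  missing <- setdiff(retained, similarity$genome_ids)
  if (length(missing) > 0L)
    stop("genomes surviving elimination are absent from the similarity matrix: ",
         paste(missing, collapse = ", "))
  W_sub <- restrict_matrix(similarity, retained)
  b <- alpha_count_vector(hits, retained, alpha)
  estimates <- correct_abundance(b, W_sub)

  structure(list(estimates = estimates, b = b, W = W_sub,
                 elimination = decisions,
                 retained_ids = retained,
                 eliminated_ids = setdiff(colnames(A), retained),
                 alpha = alpha, control = control,
                 n_reads = nrow(A), n_genomes_input = ncol(A),
                 call = match.call()),
            class = "taec")
}

#' @export
print.taec <- function(x, ...) {
  cat("Genome abundance estimate (elimination + similarity correction)\n")
  cat(sprintf("  reads: %d   genomes in alignment: %d   retained: %d   dropped in correction: %d\n",
              x$n_reads, x$n_genomes_input, length(x$retained_ids),
              sum(x$estimates$dropped_in_correction)))
  surv <- x$estimates[!x$estimates$dropped_in_correction, , drop = FALSE]
  surv <- surv[order(-surv$relative_abundance, surv$genome_id, method = "radix"), ]
  print(data.frame(genome_id = surv$genome_id,
                   corrected_count = round(surv$corrected_count, 2),
                   relative_abundance = round(surv$relative_abundance, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Summary of a fitted abundance estimate
#'
#' @param object a fitted [taec()] object.
#' @param ... unused.
#' @return A list of class `summary.taec` with the estimate table, the
#'   genome bookkeeping (input / eliminated / retained / dropped) and the
#'   control parameters in force.
#' @export
summary.taec <- function(object, ...) {
  structure(list(estimates = object$estimates,
                 elimination = object$elimination,
                 n_reads = object$n_reads,
                 n_genomes_input = object$n_genomes_input,
                 retained_ids = object$retained_ids,
                 eliminated_ids = object$eliminated_ids,
                 dropped_ids = object$estimates$genome_id[object$estimates$dropped_in_correction],
                 alpha = object$alpha, control = object$control),
            class = "summary.taec")
}

#' @export
print.summary.taec <- function(x, ...) {
  cat("Genome abundance estimation by elimination and correction\n\n")
  cat(sprintf("Reads in alignment: %d\n", x$n_reads))
  cat(sprintf("Genomes: %d in alignment output -> %d retained by elimination -> %d with positive corrected counts\n",
              x$n_genomes_input, length(x$retained_ids),
              length(x$retained_ids) - length(x$dropped_ids)))
  if (length(x$eliminated_ids) > 0)
    cat("Eliminated:", paste(x$eliminated_ids, collapse = ", "), "\n")
  if (length(x$dropped_ids) > 0)
    cat("Dropped in correction:", paste(x$dropped_ids, collapse = ", "), "\n")
  cat(sprintf("\nParameters: alpha = %g, bootstraps = %d, cutoff = %g%% of max, occurrence = %g%%\n\n",
              x$alpha, x$control$n_bootstraps, 100 * x$control$cutoff_frac,
              100 * x$control$occurrence_frac))
  surv <- x$estimates[!x$estimates$dropped_in_correction, , drop = FALSE]
  surv <- surv[order(-surv$relative_abundance, surv$genome_id, method = "radix"), ]
  print(surv, row.names = FALSE)
  invisible(x)
}

#' Extract corrected abundances from a fit
#'
#' @param object a fitted [taec()] object.
#' @param type `"counts"` for corrected read counts `t` (default) or
#'   `"proportions"` for relative abundances.
#' @param ... unused.
#' @return Named numeric vector over the surviving genomes.
#' @export
coef.taec <- function(object, type = c("counts", "proportions"), ...) {
  type <- match.arg(type)
  est <- object$estimates[!object$estimates$dropped_in_correction, , drop = FALSE]
  v <- if (type == "counts") est$corrected_count else est$relative_abundance
  stats::setNames(v, est$genome_id)
}

#' Fitted alpha-threshold counts
#'
#' Returns `W^T t` over the surviving genomes — the alpha-threshold counts
#' the fitted abundances imply.
#'
#' @param object a fitted [taec()] object.
#' @param ... unused.
#' @return Named numeric vector.
#' @export
fitted.taec <- function(object, ...) {
  surv <- object$estimates$genome_id[!object$estimates$dropped_in_correction]
  W <- restrict_matrix(object$W, surv)
  forward_counts(coef(object), W)
}

#' Residuals of the similarity system
#'
#' Observed minus fitted alpha-threshold counts, `b - W^T t`, over the
#' surviving genomes. Non-negligible residuals arise only when genomes were
#' dropped during correction (the reduced system no longer reproduces the
#' original counts exactly).
#'
#' @param object a fitted [taec()] object.
#' @param ... unused.
#' @return Named numeric vector.
#' @export
residuals.taec <- function(object, ...) {
  f <- fitted(object)
  object$b[names(f)] - f
}

#' Barplot of estimated relative abundances
#'
#' @param x a fitted [taec()] object.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.taec <- function(x, ...) {
  p <- sort(coef(x, type = "proportions"), decreasing = TRUE)
  graphics::barplot(p, ylab = "relative abundance", xlab = "genome",
                    las = 2, ...)
  invisible(x)
}
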