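new_elimination_result <- function(retained, eliminated, claimed, order_selected) {
  structure(list(retained_ids = retained, eliminated_ids = eliminated,
                 claimed_counts = claimed, order_selected = order_selected),
            class = "elimination_result")
}

#' @export
print.elimination_result <- function(x, ...) {
  cat(sprintf("Elimination: %d genome(s) retained, %d eliminated\n",
              length(x$retained_ids), length(x$eliminated_ids)))
  if (length(x$retained_ids) > 0)
    print(data.frame(genome_id = x$retained_ids,
                     claimed_reads = unname(x$claimed_counts[x$retained_ids])),
          row.names = FALSE)
  invisible(x)
}

#' Greedy unique-read elimination (iterative form)
#'
#' Every genome truly present in a sample must hold some reads no other
#' genome can explain (its unique regions), provided coverage is sufficient.
#' This procedure repeatedly selects the genome whose assignment-matrix
#' column holds the most reads, lets it claim those reads (removing them from
#' every other column), and stops when no remaining genome holds at least
#' `c` reads. Unselected genomes have no uniquely attributable support — their
#' presence in the alignment output is explainable by sequence similarity to
#' the selected genomes — and are eliminated. Ties on the column norm go to
#' the lexicographically smallest genome id (C collation) so results are
#' deterministic.
#'
#' @param A an [top_score_matrix()] result (binary read x genome matrix).
#' @param c minimum number of claimed reads for a genome to be retained
#'   (the relaxed stopping criterion; default 1).
#' @return An `elimination_result`: `retained_ids` (in selection order),
#'   `eliminated_ids` (in input column order), `claimed_counts` (named, reads
#'   claimed at selection), `order_selected`.
#' @export
eliminate_iterative <- function(A, c = 1) {
  if (c < 1) stop("c must be at least 1")
  genome_ids <- colnames(A)
  storage.mode(A) <- "logical"
  active <- rep(TRUE, nrow(A))
  remaining <- stats::setNames(seq_along(genome_ids), genome_ids)
  norms <- colSums(A)
  selected <- character(0)
  claimed <- numeric(0)
  while (length(remaining) > 0L) {
    mx <- max(norms[remaining])
    if (mx < c) break
    cand <- names(remaining)[norms[remaining] == mx]
    g <- lex_min(cand)
    jcol <- remaining[[g]]
    rows <- which(active & A[, jcol])
    selected <- c(selected, g)
    claimed <- c(claimed, mx)
    # claimed reads disappear from every column
    norms <- norms - colSums(A[rows, , drop = FALSE])
    active[rows] <- FALSE
    remaining <- remaining[names(remaining) != g]
  }
  names(claimed) <- selected
  new_elimination_result(selected,
                         genome_ids[!(genome_ids %in% selected)],
                         claimed, selected)
}

#' Greedy unique-read elimination (matrix form)
#'
#' The literal matrix formulation of the same procedure: at step j the
#' maximal-norm column is swapped into position j by a permutation matrix
#' `P_j`, a subtraction matrix `S_j` subtracts it from every later column,
#' and the result is clamped entrywise at zero,
#' `A_j = (A_{j-1} P_j S_j)_+`, until the maximal remaining column norm falls
#' below `c`. Kept alongside [eliminate_iterative()] as an executable
#' cross-check — the two are verified to produce identical results on random
#' matrices — and for exposition; the iterative form is the one used in the
#' pipeline.
#'
#' @inheritParams eliminate_iterative
#' @return An `elimination_result`, identical to [eliminate_iterative()]'s.
#' @export
eliminate_matrix_form <- function(A, c = 1) {
  if (c < 1) stop("c must be at least 1")
  input_ids <- colnames(A)
  M <- A
  class(M) <- "matrix"
  storage.mode(M) <- "double"
  attr(M, "read_ids") <- NULL
  N <- ncol(M)
  selected <- character(0)
  claimed <- numeric(0)
  j <- 1L
  while (j <= N) {
    norms <- colSums(M[, j:N, drop = FALSE])
    mx <- max(norms)
    if (mx < c) break
    cand <- colnames(M)[j:N][norms == mx]
    g <- lex_min(cand)
    pos <- which(colnames(M) == g)
    if (pos != j) {
      P <- diag(N)
      P[, c(j, pos)] <- P[, c(pos, j)]
      nm <- colnames(M)
      M <- M %*% P
      nm[c(j, pos)] <- nm[c(pos, j)]
      colnames(M) <- nm
    }
    selected <- c(selected, g)
    claimed <- c(claimed, sum(M[, j]))
    if (j < N) {
      S <- diag(N)
      S[j, (j + 1L):N] <- -1
      nm <- colnames(M)
      M <- pmax(M %*% S, 0)
      colnames(M) <- nm
    }
    j <- j + 1L
  }
  names(claimed) <- selected
  new_elimination_result(selected,
                         input_ids[!(input_ids %in% selected)],
                         claimed, selected)
}

#' Bootstrap-filtered elimination
#'
#' Runs the elimination procedure on bootstrap resamples of the reads (rows
#' of the assignment matrix, sampled with replacement) to filter out genomes
#' whose support is not robust. In each replicate a genome is *below cutoff*
#' if it is eliminated or its claimed count is less than `cutoff_frac` times
#' the replicate's maximum claimed count; a genome below cutoff in more than
#' `occurrence_frac` of the replicates is declared false and removed. The
#' defaults (100 replicates, 0.05% cutoff, 5% occurrence) are the method's
#' standard operating point.
#'
#' @param A an [top_score_matrix()] result.
#' @param n_bootstraps number of bootstrap replicates (default 100).
#' @param cutoff_frac abundance cutoff as a fraction of the most abundant
#'   genome's claimed count (default 0.0005, i.e. 0.05%).
#' @param occurrence_frac fraction of replicates above which a below-cutoff
#'   genome is removed (default 0.05).
#' @param seed optional integer seed (fixed seed gives identical results).
#' @return A list with `retained_ids` (input column order) and `decisions`,
#'   a data frame with one row per genome: `genome_id`, `n_bootstraps`,
#'   `n_below_cutoff`, `eliminated`.
#' @export
bootstrap_eliminate <- function(A, n_bootstraps = 100L, cutoff_frac = 0.0005,
                                occurrence_frac = 0.05, seed = NULL) {
  if (n_bootstraps < 1) stop("n_bootstraps must be at least 1")
  if (cutoff_frac <= 0 || cutoff_frac >= 1) stop("cutoff_frac must be in (0, 1)")
  if (occurrence_frac < 0 || occurrence_frac >= 1) stop("occurrence_frac must be in [0, 1)")
  genome_ids <- colnames(A)
  K <- nrow(A)
  n_below <- stats::setNames(integer(length(genome_ids)), genome_ids)
  with_seed(seed, {
    for (b in seq_len(n_bootstraps)) {
      idx <- sample.int(K, K, replace = TRUE)
      res <- eliminate_iterative(A[idx, , drop = FALSE], c = 1)
      cl <- stats::setNames(numeric(length(genome_ids)), genome_ids)
      cl[names(res$claimed_counts)] <- res$claimed_counts
      below <- !(genome_ids %in% res$retained_ids) | cl < cutoff_frac * max(cl)
      n_below <- n_below + below
    }
  })
  eliminated <- n_below / n_bootstraps > occurrence_frac
  if (all(eliminated))
    stop("all genomes eliminated by the bootstrap filter; consider a lower cutoff_frac")
  decisions <- data.frame(genome_id = genome_ids,
                          n_bootstraps = n_bootstraps,
                          n_below_cutoff = unname(n_below),
                          eliminated = unname(eliminated),
                          stringsAsFactors = FALSE)
  list(retained_ids = genome_ids[!eliminated], decisions = decisions)
}
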