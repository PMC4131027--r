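#' Binary top-score assignment matrix
#'
#' Builds the binary read-by-genome matrix the elimination stage consumes:
#' entry `(i, j)` is 1 when genome `j` attains read `i`'s maximum alignment
#' score. Ties within a small tolerance (1e-9) all count as top — bit scores
#' are computed values, so exact equality would be brittle. Rows follow the
#' reads' first-appearance order and columns the genomes', so the matrix is
#' deterministic for a given input file.
#'
#' @param hits a non-empty [hit_table()].
#' @param tol absolute score tolerance for counting a tie as a top score.
#' @return A logical K x N matrix of class `assignment_matrix` with genome
#'   ids as column names (row i = read i in first-appearance order).
#' @export
top_score_matrix <- function(hits, tol = 1e-9) {
  stopifnot(inherits(hits, "hit_table"))
  if (nrow(hits) == 0L) stop("hit table is empty: no assignable reads")
  read_ids <- attr(hits, "read_ids")
  genome_ids <- attr(hits, "genome_ids")
  ri <- match(hits$read_id, read_ids)
  gi <- match(hits$genome_id, genome_ids)
  rmax <- group_max(hits$score, ri, length(read_ids))
  top <- hits$score >= rmax[ri] - tol
  A <- matrix(FALSE, length(read_ids), length(genome_ids),
              dimnames = list(NULL, genome_ids))
  A[cbind(ri[top], gi[top])] <- TRUE
  attr(A, "read_ids") <- read_ids
  class(A) <- c("assignment_matrix", class(A))
  A
}

#' Alpha-threshold read counts over retained genomes
#'
#' For the correction stage: each read's hits are restricted to the retained
#' genomes, the maximum score is recomputed over that restricted set, and the
#' read is counted towards every retained genome scoring at least `alpha`
#' times that maximum (the same rule used when estimating the similarity
#' matrix, so counts and similarities are commensurable). Reads hitting only
#' eliminated genomes contribute nothing.
#'
#' @param hits a [hit_table()].
#' @param genome_ids the retained genome ids (non-empty).
#' @param alpha threshold fraction in `[0, 1]`.
#' @return Named numeric vector `b` of per-genome read counts, in the order
#'   of `genome_ids`.
#' @export
alpha_count_vector <- function(hits, genome_ids, alpha) {
  stopifnot(inherits(hits, "hit_table"))
  if (length(genome_ids) == 0L) stop("retained genome set is empty")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  sub <- hits[hits$genome_id %in% genome_ids, , drop = FALSE]
  b <- stats::setNames(numeric(length(genome_ids)), genome_ids)
  if (nrow(sub) == 0L) return(b)
  rid <- unique(sub$read_id)
  ri <- match(sub$read_id, rid)
  rmax <- group_max(sub$score, ri, length(rid))
  qual <- sub$score >= alpha * rmax[ri] - 1e-9
  tab <- table(factor(sub$genome_id[qual], levels = genome_ids))
  b[] <- as.numeric(tab)
  b
}
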