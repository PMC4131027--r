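#' Construct a genome-similarity matrix
#'
#' Entry `W[j, j']` estimates the probability that a read originating from
#' genome `j` is assigned (under the alpha-threshold rule) to genome `j'`.
#' The diagonal is exactly 1, off-diagonal entries are either 0 or at least
#' `threshold`, and the matrix need not be symmetric.
#'
#' @param W square numeric matrix with matching row/column genome-id dimnames.
#' @param read_length read length (bp) the matrix was built for.
#' @param K0 number of simulated reads per source genome used to build it.
#' @param alpha alpha-threshold used in the multi-assignment rule.
#' @param threshold similarity values below this were zeroed.
#' @return An object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(W, read_length, K0, alpha, threshold) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("similarity matrix must be square")
  ids <- rownames(W)
  if (is.null(ids) || !identical(ids, colnames(W)))
    stop("similarity matrix needs matching row and column genome ids")
  if (any(W < 0) || any(W > 1)) stop("similarity values must lie in [0, 1]")
  if (any(abs(diag(W) - 1) > 0)) stop("similarity matrix diagonal must equal 1")
  off <- W[row(W) != col(W)]
  if (any(off != 0 & off < threshold))
    stop("off-diagonal similarities must be 0 or >= threshold")
  structure(list(genome_ids = ids, W = W,
                 read_length = as.numeric(read_length), K0 = as.numeric(K0),
                 alpha = as.numeric(alpha), threshold = as.numeric(threshold)),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("Genome similarity matrix: %d genomes (read length %g bp, K0 = %g, alpha = %g, threshold = %g)\n",
              length(x$genome_ids), x$read_length, x$K0, x$alpha, x$threshold))
  m <- min(6L, length(x$genome_ids))
  print(round(x$W[seq_len(m), seq_len(m), drop = FALSE], 4))
  if (length(x$genome_ids) > m) cat("...\n")
  invisible(x)
}

#' Alpha-threshold read assignment
#'
#' A read aligned to several genomes is assigned to every genome whose score
#' is at least `alpha` times the read's maximum score. The arg-max genome
#' always qualifies; with `alpha = 0` every hit genome qualifies.
#'
#' @param scores named numeric vector of alignment scores for one read
#'   (names are genome ids).
#' @param alpha threshold fraction in `[0, 1]`.
#' @return Character vector of assigned genome ids (empty if `scores` is empty).
#' @export
alpha_assign <- function(scores, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (length(scores) == 0L) return(character(0))
  # small absolute slack so that e.g. 96 >= 0.96 * 100 holds despite FP rounding
  names(scores)[scores >= alpha * max(scores) - 1e-9]
}

# Count alpha-threshold assignments per genome over a whole hit table.
# Returns a named numeric vector over `genome_ids` (0 for unseen genomes).
alpha_assignment_counts <- function(hits, genome_ids, alpha) {
  n <- stats::setNames(numeric(length(genome_ids)), genome_ids)
  if (nrow(hits) == 0L) return(n)
  rid <- attr(hits, "read_ids")
  ri <- match(hits$read_id, rid)
  rmax <- group_max(hits$score, ri, length(rid))
  qual <- hits$score >= alpha * rmax[ri] - 1e-9
  tab <- table(factor(hits$genome_id[qual], levels = genome_ids))
  n[] <- as.numeric(tab)
  n
}

#' Estimate the genome-similarity matrix from simulated reads
#'
#' For each source genome, `K0` error-free reads of length `read_length` are
#' simulated at uniform positions and aligned against all genomes; each read
#' is multi-assigned by the alpha-threshold rule. With `n[j, j']` the number
#' of genome-`j` reads assigned to genome `j'`, the similarity is
#' `w[j, j'] = n[j, j'] / n[j, j]` (clamped to at most 1), entries below
#' `threshold` are zeroed, and the diagonal is set to 1. The alternative
#' normalization by `K0` is available via `normalize = "k0"`.
#'
#' @param genomes named character vector of genome sequences.
#' @param read_length simulated read length (bp).
#' @param K0 reads per source genome (default 30000).
#' @param alpha alpha-threshold (default 0.96).
#' @param threshold similarity floor below which entries are zeroed
#'   (default 0.001).
#' @param aligner function `(reads, genomes) -> hit_table`; defaults to the
#'   built-in k-mer seed aligner.
#' @param seed integer seed for read simulation (default 7771).
#' @param normalize `"self"` (divide by the self-assigned count, default) or
#'   `"k0"` (divide by `K0`).
#' @return A [similarity_matrix()].
#' @export
estimate_similarity <- function(genomes, read_length, K0 = 30000L, alpha = 0.96,
                                threshold = 0.001, aligner = NULL, seed = 7771L,
                                normalize = c("self", "k0")) {
  normalize <- match.arg(normalize)
  if (K0 < 1) stop("K0 must be at least 1")
  if (any(nchar(genomes) < read_length))
    stop("all genomes must be at least read_length long")
  if (is.null(aligner)) aligner <- function(reads, gs) naive_align(reads, gs)
  ids <- names(genomes)
  m <- length(ids)
  W <- matrix(0, m, m, dimnames = list(ids, ids))
  with_seed(seed, {
    for (j in seq_len(m)) {
      rd <- sample_reads_one(genomes[[j]], K0, read_length)
      reads <- stats::setNames(rd$seq, sprintf("simread%d", seq_len(K0)))
      hits <- aligner(reads, genomes)
      W[j, ] <- alpha_assignment_counts(hits, ids, alpha)
    }
  })
  self <- diag(W)
  if (any(self == 0))
    stop("no simulated read maps back to its own genome (degenerate reference): ",
         ids[self == 0][1L])
  W <- if (normalize == "self") W / self else W / K0
  W <- pmin(W, 1)
  W[W < threshold] <- 0
  diag(W) <- 1
  similarity_matrix(W, read_length = read_length, K0 = K0,
                    alpha = alpha, threshold = threshold)
}

#' Estimate similarity from precomputed per-genome alignment results
#'
#' For workflows that align the similarity reads with an external tool: given
#' one hit table per source genome (e.g. parsed from BLAST tabular output via
#' [parse_blast_tabular()]), performs only the alpha-threshold assignment,
#' counting and normalization steps of [estimate_similarity()].
#'
#' @param hits_by_source named list of [hit_table()]s, one per source genome,
#'   named by source genome id; each holds the alignments of that genome's
#'   simulated reads against all genomes.
#' @param genome_ids the full ordered set of genome ids for the matrix.
#' @param read_length,K0,alpha,threshold,normalize as in [estimate_similarity()].
#' @return A [similarity_matrix()].
#' @export
similarity_from_hits <- function(hits_by_source, genome_ids, read_length,
                                 K0, alpha = 0.96, threshold = 0.001,
                                 normalize = c("self", "k0")) {
  normalize <- match.arg(normalize)
  src <- names(hits_by_source)
  if (is.null(src) || !all(src %in% genome_ids))
    stop("hits_by_source must be named by source genome ids present in genome_ids")
  m <- length(genome_ids)
  W <- matrix(0, m, m, dimnames = list(genome_ids, genome_ids))
  for (j in src)
    W[j, ] <- alpha_assignment_counts(hits_by_source[[j]], genome_ids, alpha)
  self <- diag(W)
  if (any(self == 0))
    stop("no read maps back to its own genome (degenerate reference): ",
         genome_ids[self == 0][1L])
  W <- if (normalize == "self") W / self else W / K0
  W <- pmin(W, 1)
  W[W < threshold] <- 0
  diag(W) <- 1
  similarity_matrix(W, read_length = read_length, K0 = K0,
                    alpha = alpha, threshold = threshold)
}

#' Select the similarity matrix matching a sample's read length
#'
#' Similarity depends on read length, so the matrix built at the read length
#' closest to the sample's mean read length should be used. Ties go to the
#' shorter read length.
#'
#' @param available list of [similarity_matrix()] objects.
#' @param mean_read_length the sample's mean read length (bp).
#' @return The selected [similarity_matrix()].
#' @export
select_matrix_by_read_length <- function(available, mean_read_length) {
  if (length(available) == 0L) stop("no similarity matrices available")
  rl <- vapply(available, function(m) m$read_length, numeric(1))
  d <- abs(rl - mean_read_length)
  cand <- which(d == min(d))
  available[[cand[which.min(rl[cand])]]]
}

#' Restrict a similarity matrix to a genome subset
#'
#' Returns the principal submatrix over the requested genomes, in the
#' requested order, with metadata preserved. Used to carry the matrix of the
#' genomes surviving elimination into the correction stage.
#'
#' @param matrix a [similarity_matrix()].
#' @param genome_ids non-empty subset of the matrix's genome ids.
#' @return A [similarity_matrix()] over `genome_ids`.
#' @export
restrict_matrix <- function(matrix, genome_ids) {
  stopifnot(inherits(matrix, "similarity_matrix"))
  if (length(genome_ids) == 0L) stop("cannot restrict to an empty genome set")
  unknown <- setdiff(genome_ids, matrix$genome_ids)
  if (length(unknown) > 0L)
    stop("genome ids not in similarity matrix: ", paste(unknown, collapse = ", "))
  similarity_matrix(matrix$W[genome_ids, genome_ids, drop = FALSE],
                    read_length = matrix$read_length, K0 = matrix$K0,
                    alpha = matrix$alpha, threshold = matrix$threshold)
}
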