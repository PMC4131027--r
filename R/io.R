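#' Construct a hit table
#'
#' A hit table is the package's representation of a read-vs-genome alignment
#' result: one row per (read, genome) pair with the best alignment score for
#' that pair. Duplicate (read, genome) pairs in the input are collapsed to
#' their maximum score, since the method's unit of evidence is the pair, not
#' the individual HSP. The first-appearance order of read and genome ids is
#' preserved so that downstream matrices are deterministic.
#'
#' @param read_id character vector of read identifiers.
#' @param genome_id character vector of genome (subject) identifiers.
#' @param score numeric vector of non-negative alignment scores.
#' @return An object of class `hit_table`: a data frame with columns
#'   `read_id`, `genome_id`, `score` and attributes `read_ids`, `genome_ids`
#'   (unique ids in first-appearance order).
#' @examples
#' h <- hit_table(c("r1", "r1", "r2"), c("G1", "G2", "G2"), c(100, 96, 100))
#' attr(h, "genome_ids")
#' @export
hit_table <- function(read_id, genome_id, score) {
  read_id <- as.character(read_id)
  genome_id <- as.character(genome_id)
  score <- as.numeric(score)
  n <- length(read_id)
  if (length(genome_id) != n || length(score) != n)
    stop("read_id, genome_id and score must have equal length")
  if (n > 0L) {
    if (anyNA(score) || any(score < 0)) stop("scores must be non-negative and non-missing")
    if (any(!nzchar(read_id)) || any(!nzchar(genome_id)))
      stop("read_id and genome_id must be non-empty strings")
  }
  read_ids <- unique(read_id)
  genome_ids <- unique(genome_id)
  if (n > 0L) {
    ri <- match(read_id, read_ids)
    gi <- match(genome_id, genome_ids)
    # keep the max score per (read, genome) pair
    key <- (ri - 1) * length(genome_ids) + gi
    o <- order(key, -score)
    keep <- o[!duplicated(key[o])]
    keep <- sort(keep)  # retain input row order among survivors
    df <- data.frame(read_id = read_id[keep], genome_id = genome_id[keep],
                     score = score[keep], stringsAsFactors = FALSE)
  } else {
    df <- data.frame(read_id = character(0), genome_id = character(0),
                     score = numeric(0), stringsAsFactors = FALSE)
  }
  structure(df, read_ids = read_ids, genome_ids = genome_ids,
            class = c("hit_table", "data.frame"))
}

#' @export
print.hit_table <- function(x, ...) {
  cat(sprintf("Hit table: %d hits, %d reads, %d genomes\n",
              nrow(x), length(attr(x, "read_ids")), length(attr(x, "genome_ids"))))
  if (nrow(x) > 0) print.data.frame(head(x, 10L), row.names = FALSE)
  if (nrow(x) > 10) cat(sprintf("... and %d more hits\n", nrow(x) - 10L))
  invisible(x)
}

#' Parse BLAST tabular alignment output
#'
#' Reads BLAST tabular output (`-outfmt 6`; the commented variant `-outfmt 7`
#' is tolerated, `#` lines are skipped) into a [hit_table()]. The query id is
#' taken as the read id and the subject id, verbatim, as the genome id. When a
#' read has several HSPs against the same genome only the best score is kept.
#'
#' @param path path to a BLAST tabular file.
#' @param score_column 1-based column holding the alignment score. Defaults to
#'   12, the bit score, which is length-normalized and therefore comparable
#'   across genomes as the alpha-threshold assignment rule requires.
#' @return A [hit_table()]. An empty file yields an empty hit table.
#' @export
parse_blast_tabular <- function(path, score_column = 12L) {
  if (!file.exists(path)) stop("file not found: ", path)
  score_column <- as.integer(score_column)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(hit_table(character(0), character(0), numeric(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < max(12L, score_column))
  if (length(bad) > 0L)
    stop(sprintf("malformed BLAST tabular line %d: expected >= 12 tab-separated fields, got %d",
                 lineno[bad[1L]], nf[bad[1L]]))
  qid <- vapply(fields, `[[`, "", 1L)
  sid <- vapply(fields, `[[`, "", 2L)
  sc <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", score_column)))
  if (anyNA(sc)) {
    bad <- which(is.na(sc))[1L]
    stop(sprintf("malformed BLAST tabular line %d: non-numeric score in column %d",
                 lineno[bad], score_column))
  }
  hit_table(qid, sid, sc)
}

#' Read genome sequences from a FASTA file
#'
#' @param path path to a FASTA file.
#' @return A named character vector of uppercase sequences over `{A,C,G,T,N}`,
#'   named by the FASTA header truncated at the first whitespace.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("illegal character in sequence of record '", ids[bad][1L],
         "' (only A, C, G, T, N allowed)")
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write an abundance report
#'
#' Writes the corrected abundance estimates of the surviving (non-dropped)
#' genomes as a three-column TSV (`genome_id`, `corrected_read_count`,
#' `relative_abundance`), sorted by descending relative abundance with ties
#' broken by ascending genome id.
#'
#' @param estimates an abundance estimate data frame as returned by
#'   [correct_abundance()] (or the `estimates` component of a fitted
#'   [taec()] object).
#' @param path output path.
#' @export
write_abundance_table <- function(estimates, path) {
  est <- as.data.frame(estimates)
  if ("dropped_in_correction" %in% names(est))
    est <- est[!est$dropped_in_correction, , drop = FALSE]
  if (nrow(est) == 0L) stop("no surviving genomes to write")
  if (abs(sum(est$relative_abundance) - 1) > 1e-9)
    stop("relative abundances must sum to 1")
  o <- order(-est$relative_abundance, est$genome_id, method = "radix")
  est <- est[o, c("genome_id", "corrected_count", "relative_abundance")]
  names(est)[2L] <- "corrected_read_count"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(est), collapse = "\t"), con)
  body <- sprintf("%s\t%.17g\t%.17g", est$genome_id,
                  est$corrected_read_count, est$relative_abundance)
  writeLines(body, con)
  invisible(path)
}

#' Read a genome-similarity matrix from a TSV file
#'
#' The format is the one produced by [write_similarity_matrix()]: `#`-prefixed
#' metadata lines (`read_length`, `K0`, `alpha`, `threshold`), then a header
#' row of genome ids and one row per genome (row = source genome).
#'
#' @param path path to a similarity-matrix TSV.
#' @return A [similarity_matrix()] object.
#' @export
read_similarity_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([A-Za-z0-9_]+)\\s*[:=]\\s*(\\S+)", ml))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- as.numeric(m[3L])
  }
  need <- c("read_length", "K0", "alpha", "threshold")
  if (!all(need %in% names(meta)))
    stop("similarity matrix file missing metadata: ",
         paste(setdiff(need, names(meta)), collapse = ", "))
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(body) < 2L) stop("similarity matrix file has no body")
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  ids <- header[-1L]
  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  if (any(lengths(rows) != length(ids) + 1L))
    stop("similarity matrix body is not square: row/column count mismatch")
  row_ids <- vapply(rows, `[[`, "", 1L)
  if (length(row_ids) != length(ids) || !identical(row_ids, ids))
    stop("similarity matrix row ids do not match column ids")
  W <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1L])))
  if (anyNA(W)) stop("non-numeric entry in similarity matrix body")
  dimnames(W) <- list(ids, ids)
  similarity_matrix(W, read_length = meta$read_length, K0 = meta$K0,
                    alpha = meta$alpha, threshold = meta$threshold)
}

#' Write a genome-similarity matrix to a TSV file
#'
#' Full stored precision is preserved so that `read(write(M))` is an exact
#' round trip.
#'
#' @param matrix a [similarity_matrix()] object.
#' @param path output path.
#' @export
write_similarity_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "similarity_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# read_length: %.17g", matrix$read_length),
               sprintf("# K0: %.17g", matrix$K0),
               sprintf("# alpha: %.17g", matrix$alpha),
               sprintf("# threshold: %.17g", matrix$threshold)), con)
  ids <- matrix$genome_ids
  writeLines(paste(c("genome_id", ids), collapse = "\t"), con)
  for (i in seq_along(ids)) {
    writeLines(paste(c(ids[i], sprintf("%.17g", matrix$W[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}
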