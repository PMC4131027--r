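BASES <- c("A", "C", "G", "T")

#' Generate a random genome sequence
#'
#' Bases are i.i.d. uniform over A/C/G/T, so two independently generated
#' genomes share essentially no k-mers of seed length and behave as completely
#' dissimilar reference genomes.
#'
#' @param length genome length in bp.
#' @param seed optional integer seed; the caller's RNG state is untouched.
#' @param id genome identifier for the returned named vector.
#' @return A length-1 named character vector (the sequence, named by `id`).
#' @export
generate_genome <- function(length, seed = NULL, id = "g1") {
  if (!is.numeric(length) || length < 1) stop("genome length must be positive")
  seq <- with_seed(seed, paste(sample(BASES, length, replace = TRUE), collapse = ""))
  stats::setNames(seq, id)
}

# Substitute, at positions given by `pos`, a base different from the original
# (uniform over the other three).
substitute_bases <- function(chars, pos) {
  if (length(pos) == 0L) return(chars)
  code <- match(chars[pos], BASES) - 1L
  code[is.na(code)] <- sample.int(4L, sum(is.na(code)), replace = TRUE) - 1L  # N -> random base
  offs <- sample.int(3L, length(pos), replace = TRUE)
  chars[pos] <- BASES[((code + offs) %% 4L) + 1L]
  chars
}

#' Derive a mutant genome by random substitutions
#'
#' Each position is independently replaced by a *different* base with the
#' given probability, producing a controllable level of sequence similarity
#' between the base genome and its mutant — the mechanism used to emulate
#' closely related species or strains in synthetic communities.
#'
#' @param base a length-1 named character vector (as from [generate_genome()]).
#' @param substitution_rate per-position substitution probability in `[0, 1]`.
#' @param seed optional integer seed.
#' @param id identifier for the mutant.
#' @return A length-1 named character vector.
#' @export
mutate_genome <- function(base, substitution_rate, seed = NULL, id = NULL) {
  stopifnot(length(base) == 1L)
  if (substitution_rate < 0 || substitution_rate > 1)
    stop("substitution_rate must be in [0, 1]")
  if (is.null(id)) id <- paste0(names(base), "_mut")
  chars <- strsplit(base[[1L]], "", fixed = TRUE)[[1L]]
  seq <- with_seed(seed, {
    pos <- which(runif(length(chars)) < substitution_rate)
    paste(substitute_bases(chars, pos), collapse = "")
  })
  stats::setNames(seq, id)
}

#' Allocate integer read counts from proportions (largest remainder)
#'
#' Deterministic largest-remainder apportionment: floor each share, then give
#' the leftover reads to the largest fractional remainders (ties to the
#' earlier genome). Used so that true per-genome counts are exact and error
#' metrics carry no allocation noise.
#'
#' @param proportions non-negative proportions summing to 1.
#' @param total total number of reads.
#' @return Integer vector of counts summing to `total`.
#' @export
allocate_counts <- function(proportions, total) {
  if (abs(sum(proportions) - 1) > 1e-9 || any(proportions < 0))
    stop("proportions must be non-negative and sum to 1")
  raw <- proportions * total
  counts <- floor(raw)
  rem <- total - sum(counts)
  if (rem > 0) {
    o <- order(-(raw - counts), seq_along(raw))
    counts[o[seq_len(rem)]] <- counts[o[seq_len(rem)]] + 1
  }
  as.integer(counts)
}

#' Define a synthetic community
#'
#' Bundles the genomes, true proportions and derived exact read counts that
#' the read simulator and the evaluation metrics share.
#'
#' @param genomes named character vector of genome sequences.
#' @param proportions per-genome proportions summing to 1.
#' @param total_reads total number of reads to simulate.
#' @param read_length read length in bp.
#' @param error_rate per-base substitution error rate in `[0, 1)`.
#' @param seed integer seed for read simulation.
#' @param allocation `"exact"` (largest remainder, default) or `"multinomial"`.
#' @return An object of class `synthetic_community` with components `genomes`,
#'   `proportions`, `true_counts` (named integer vector), `read_length`,
#'   `error_rate`, `seed`.
#' @export
synthetic_community <- function(genomes, proportions, total_reads,
                                read_length = 100L, error_rate = 0,
                                seed = 1L, allocation = c("exact", "multinomial")) {
  allocation <- match.arg(allocation)
  if (length(genomes) != length(proportions))
    stop("genomes and proportions must have equal length")
  if (abs(sum(proportions) - 1) > 1e-9 || any(proportions < 0))
    stop("proportions must be non-negative and sum to 1 (got sum = ",
         format(sum(proportions)), ")")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  if (read_length < 1) stop("read_length must be positive")
  short <- nchar(genomes) < read_length
  if (any(short))
    stop("genome shorter than read_length: ", names(genomes)[short][1L])
  counts <- if (allocation == "exact") {
    allocate_counts(proportions, total_reads)
  } else {
    with_seed(seed, as.integer(stats::rmultinom(1L, total_reads, proportions)[, 1L]))
  }
  structure(list(genomes = genomes,
                 proportions = stats::setNames(proportions, names(genomes)),
                 true_counts = stats::setNames(counts, names(genomes)),
                 read_length = as.integer(read_length),
                 error_rate = error_rate, seed = seed),
            class = "synthetic_community")
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat(sprintf("Synthetic community: %d genomes, %d reads of %d bp, error rate %g\n",
              length(x$genomes), sum(x$true_counts), x$read_length, x$error_rate))
  print(data.frame(genome_id = names(x$genomes),
                   length_bp = unname(nchar(x$genomes)),
                   proportion = unname(x$proportions),
                   true_count = unname(x$true_counts)), row.names = FALSE)
  invisible(x)
}

# Uniform error-free reads from one genome; internal building block shared by
# simulate_reads and the similarity estimator.
sample_reads_one <- function(seq, n, read_length) {
  L <- nchar(seq)
  starts <- sample.int(L - read_length + 1L, n, replace = TRUE) - 1L
  list(seq = substring(seq, starts + 1L, starts + read_length), start = starts)
}

#' Simulate reads from a synthetic community
#'
#' Per-genome read counts follow the community's `true_counts` exactly; start
#' positions are uniform on the forward strand (genomes treated as linear) and
#' substitution errors are applied independently per base at the community's
#' `error_rate`.
#'
#' @param community a [synthetic_community()].
#' @return A data frame of class `simulated_reads` with columns `read_id`
#'   (encoding origin and position as `readN|origin=g|pos=p`),
#'   `origin_genome_id`, `sequence`, `start`.
#' @export
simulate_reads <- function(community) {
  stopifnot(inherits(community, "synthetic_community"))
  rl <- community$read_length
  with_seed(community$seed, {
    parts <- lapply(seq_along(community$genomes), function(i) {
      n <- community$true_counts[i]
      if (n == 0L) return(NULL)
      gid <- names(community$genomes)[i]
      rd <- sample_reads_one(community$genomes[[i]], n, rl)
      if (community$error_rate > 0) {
        nerr <- rbinom(n, rl, community$error_rate)
        todo <- which(nerr > 0L)
        for (j in todo) {
          chars <- strsplit(rd$seq[j], "", fixed = TRUE)[[1L]]
          pos <- sample.int(rl, nerr[j])
          rd$seq[j] <- paste(substitute_bases(chars, pos), collapse = "")
        }
      }
      data.frame(origin_genome_id = gid, sequence = rd$seq, start = rd$start,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, parts)
    if (is.null(out)) stop("community has no reads")
    out <- cbind(read_id = sprintf("read%d|origin=%s|pos=%d",
                                   seq_len(nrow(out)), out$origin_genome_id, out$start),
                 out)
    class(out) <- c("simulated_reads", "data.frame")
    out
  })
}

#' Align reads against genomes with the built-in k-mer seed aligner
#'
#' A deterministic seed-and-extend aligner: every k-mer shared between a read
#' and a genome proposes a diagonal placement, each placement is scored as a
#' full-length ungapped alignment (`match` per matching base, `mismatch` per
#' mismatching base), and the genome's best score is kept. A hit is emitted
#' only when the best score is positive. This is the in-process stand-in for
#' an external aligner such as BLASTN: it reports comparable scores per
#' (read, genome) pair, which is all the downstream method consumes.
#'
#' @param reads a `simulated_reads` data frame, or a named character vector of
#'   read sequences.
#' @param genomes named character vector of genome sequences.
#' @param k seed length (default 16).
#' @param match match score (default 1).
#' @param mismatch mismatch penalty, non-positive (default -2).
#' @return A [hit_table()].
#' @export
naive_align <- function(reads, genomes, k = 16L, match = 1, mismatch = -2) {
  if (inherits(reads, "simulated_reads") || is.data.frame(reads)) {
    read_ids <- reads$read_id
    read_seqs <- reads$sequence
  } else {
    read_seqs <- unname(reads)
    read_ids <- names(reads)
    if (is.null(read_ids)) read_ids <- sprintf("read%d", seq_along(read_seqs))
  }
  if (match <= 0) stop("match score must be positive")
  if (mismatch > 0) stop("mismatch penalty must be <= 0")
  if (length(read_seqs) > 0 && k > min(nchar(read_seqs)))
    stop("seed length k exceeds the shortest read length")
  res <- .kmer_align_cpp(read_seqs, unname(genomes), as.integer(k),
                         as.numeric(match), as.numeric(mismatch))
  hit_table(read_ids[res$read], names(genomes)[res$genome], res$score)
}

#' Simulate a full sample to disk
#'
#' Convenience wrapper that simulates a community's reads, aligns them with
#' the built-in aligner, and writes the four artifacts an external workflow
#' would produce: the genomes FASTA, the reads FASTA, a truth table
#' (`genome_id`, `true_count`) and the alignment hits in BLAST-like tabular
#' form (read id, genome id, score in the bit-score column).
#'
#' @param community a [synthetic_community()].
#' @param out_dir output directory (created if needed).
#' @param k,match,mismatch aligner parameters, see [naive_align()].
#' @return Invisibly, a named list of the four file paths.
#' @export
simulate_sample <- function(community, out_dir, k = 16L, match = 1, mismatch = -2) {
  stopifnot(inherits(community, "synthetic_community"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(genomes = file.path(out_dir, "genomes.fasta"),
                reads = file.path(out_dir, "reads.fasta"),
                truth = file.path(out_dir, "truth.tsv"),
                hits = file.path(out_dir, "hits.tsv"))
  write_fasta(community$genomes, paths$genomes)
  reads <- simulate_reads(community)
  write_fasta(stats::setNames(reads$sequence, reads$read_id), paths$reads)
  truth <- data.frame(genome_id = names(community$true_counts),
                      true_count = unname(community$true_counts))
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  hits <- naive_align(reads, community$genomes, k = k, match = match, mismatch = mismatch)
  # 12-column BLAST-like tabular layout; only columns 1, 2 and 12 are meaningful
  lines <- sprintf("%s\t%s\t0\t0\t0\t0\t0\t0\t0\t0\t0\t%.17g",
                   hits$read_id, hits$genome_id, hits$score)
  writeLines(lines, paths$hits)
  invisible(paths)
}
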