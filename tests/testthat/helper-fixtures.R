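# Shared fixtures, all built in code.

# Synthetic reconstruction of a minimal six-read alignment in BLAST tabular
# form: four genomes of which G1 and G2 attract only reads that G3 (or G4)
# explains equally well, while G3 and G4 each hold reads of their own.
# Running elimination with c = 1 on its top-score matrix retains exactly
# {G3, G4}.
six_read_blast_lines <- function() {
  hits <- list(
    r1 = c(G1 = 100, G3 = 100),
    r2 = c(G1 = 100, G3 = 100),
    r3 = c(G2 = 100, G3 = 100),
    r4 = c(G3 = 100),
    r5 = c(G2 = 100, G4 = 100),
    r6 = c(G4 = 100))
  unlist(lapply(names(hits), function(r) {
    sprintf("%s\t%s\t100.00\t100\t0\t0\t1\t100\t1\t100\t1e-50\t%.1f",
            r, names(hits[[r]]), hits[[r]])
  }))
}

write_six_read_blast <- function() {
  path <- tempfile(fileext = ".tsv")
  writeLines(six_read_blast_lines(), path)
  path
}

# Random binary assignment matrix with every row non-empty.
random_assignment_matrix <- function(K, N, density = 0.3) {
  A <- matrix(runif(K * N) < density, K, N,
              dimnames = list(NULL, sprintf("g%02d", seq_len(N))))
  empty <- which(rowSums(A) == 0L)
  if (length(empty) > 0L)
    A[cbind(empty, sample.int(N, length(empty), replace = TRUE))] <- TRUE
  class(A) <- c("assignment_matrix", class(A))
  A
}

# Random valid similarity matrix: diagonal 1, sparse off-diagonal entries in
# [threshold, max_off].
random_similarity <- function(m, max_off = 0.3, threshold = 0.001,
                              read_length = 100, K0 = 1000, alpha = 0.96) {
  W <- matrix(0, m, m)
  off <- row(W) != col(W)
  active <- off & (matrix(runif(m * m), m, m) < 0.5)
  W[active] <- runif(sum(active), threshold, max_off)
  diag(W) <- 1
  ids <- sprintf("g%02d", seq_len(m))
  dimnames(W) <- list(ids, ids)
  similarity_matrix(W, read_length = read_length, K0 = K0, alpha = alpha,
                    threshold = threshold)
}

# Identity similarity matrix over the given ids.
identity_similarity <- function(ids, read_length = 100) {
  W <- diag(length(ids))
  dimnames(W) <- list(ids, ids)
  similarity_matrix(W, read_length = read_length, K0 = 1000, alpha = 0.96,
                    threshold = 0.001)
}

expect_same_elimination <- function(a, b) {
  expect_identical(a$retained_ids, b$retained_ids)
  expect_identical(sort(a$eliminated_ids), sort(b$eliminated_ids))
  expect_equal(a$claimed_counts, b$claimed_counts)
  expect_identical(a$order_selected, b$order_selected)
}
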