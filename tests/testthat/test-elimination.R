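as_A <- function(..., ids) {
  A <- rbind(...)
  colnames(A) <- ids
  storage.mode(A) <- "logical"
  A
}

test_that("greedy elimination claims reads and removes unsupported genomes", {
  # each read hits exactly one genome: everything retained
  A1 <- as_A(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), ids = c("G1", "G2", "G3"))
  r1 <- eliminate_iterative(A1, c = 1)
  expect_setequal(r1$retained_ids, c("G1", "G2", "G3"))
  expect_equal(unname(r1$claimed_counts), rep(1, 3))

  # r1->{G1,G2}, r2->{G2}, r3->{G2,G3}, r4->{G3}: G2 claims 3, G3 claims 1,
  # G1 is left with nothing
  A2 <- as_A(c(1, 1, 0), c(0, 1, 0), c(0, 1, 1), c(0, 0, 1),
             ids = c("G1", "G2", "G3"))
  r2 <- eliminate_iterative(A2, c = 1)
  expect_identical(r2$retained_ids, c("G2", "G3"))
  expect_identical(r2$eliminated_ids, "G1")
  expect_equal(r2$claimed_counts, c(G2 = 3, G3 = 1))
  expect_identical(r2$order_selected, c("G2", "G3"))

  # ties on the column norm break to the lexicographically smallest id
  A3 <- as_A(c(1, 1), ids = c("Gb", "Ga"))
  expect_identical(eliminate_iterative(A3, c = 1)$retained_ids, "Ga")
})

test_that("matrix-form elimination matches on simple cases", {
  A <- as_A(1, 1, 1, ids = "G1")
  r <- eliminate_matrix_form(A, c = 1)
  expect_identical(r$retained_ids, "G1")
  expect_equal(unname(r$claimed_counts), 3)

  A2 <- as_A(c(1, 1, 0), c(0, 1, 0), c(0, 1, 1), c(0, 0, 1),
             ids = c("G1", "G2", "G3"))
  expect_same_elimination(eliminate_matrix_form(A2, c = 1),
                          eliminate_iterative(A2, c = 1))
})

test_that("matrix-form and iterative elimination agree on random inputs", {
  set.seed(121)
  for (i in 1:200) {
    K <- sample(1:50, 1)
    N <- sample(1:10, 1)
    A <- random_assignment_matrix(K, N)
    c0 <- sample(1:3, 1)
    expect_same_elimination(eliminate_matrix_form(A, c = c0),
                            eliminate_iterative(A, c = c0))
  }
})

test_that("elimination obeys claim conservation, c-monotonicity and uniqueness", {
  set.seed(122)
  for (i in 1:50) {
    K <- sample(5:60, 1)
    N <- sample(2:8, 1)
    A <- random_assignment_matrix(K, N)
    r1 <- eliminate_iterative(A, c = 1)
    expect_lte(sum(r1$claimed_counts), K)

    # monotone in c: larger threshold retains a subset
    r3 <- eliminate_iterative(A, c = 3)
    expect_true(all(r3$retained_ids %in% r1$retained_ids))

    # uniquely supported genomes can never be eliminated
    unique_rows <- rowSums(A) == 1
    u <- colSums(A & unique_rows)
    expect_true(all(colnames(A)[u >= 1] %in% r1$retained_ids))
    expect_true(all(colnames(A)[u >= 3] %in% r3$retained_ids))
  }
})

test_that("bootstrap filtering keeps robust genomes and removes spurious ones", {
  # single genome: always retained, never below cutoff
  A1 <- as_A(1, 1, 1, 1, ids = "G1")
  b1 <- bootstrap_eliminate(A1, n_bootstraps = 10, seed = 1)
  expect_identical(b1$retained_ids, "G1")
  expect_equal(b1$decisions$n_below_cutoff, 0L)
  expect_equal(b1$decisions$n_bootstraps, 10L)

  # two well-supported dissimilar genomes (1000 and 500 unique reads):
  # both retained in every replicate
  A2 <- matrix(FALSE, 1500, 2, dimnames = list(NULL, c("G1", "G2")))
  A2[1:1000, 1] <- TRUE
  A2[1001:1500, 2] <- TRUE
  b2 <- bootstrap_eliminate(A2, n_bootstraps = 30, cutoff_frac = 0.0005, seed = 2)
  expect_setequal(b2$retained_ids, c("G1", "G2"))
  expect_equal(b2$decisions$n_below_cutoff, c(0L, 0L))

  # a genome with 1 read among 10,000 falls below the 0.05% cutoff whenever
  # present and is eliminated
  A3 <- matrix(FALSE, 10000, 2, dimnames = list(NULL, c("Gbig", "Gtiny")))
  A3[1:9999, 1] <- TRUE
  A3[10000, 2] <- TRUE
  b3 <- bootstrap_eliminate(A3, n_bootstraps = 100, cutoff_frac = 0.0005,
                            occurrence_frac = 0.05, seed = 3)
  expect_identical(b3$retained_ids, "Gbig")
  expect_true(b3$decisions$eliminated[b3$decisions$genome_id == "Gtiny"])

  # decisions satisfy the defining inequality
  expect_equal(b3$decisions$eliminated,
               b3$decisions$n_below_cutoff / b3$decisions$n_bootstraps > 0.05)
})

test_that("bootstrap elimination is deterministic under a fixed seed", {
  set.seed(123)
  A <- random_assignment_matrix(200, 5)
  r1 <- bootstrap_eliminate(A, n_bootstraps = 25, seed = 99)
  r2 <- bootstrap_eliminate(A, n_bootstraps = 25, seed = 99)
  expect_identical(r1, r2)
})
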