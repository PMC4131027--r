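test_that("alpha-threshold assignment follows the score-ratio rule", {
  expect_setequal(alpha_assign(c(G1 = 100, G2 = 96, G3 = 80), 0.96), c("G1", "G2"))
  expect_setequal(alpha_assign(c(G1 = 10, G2 = 1, G3 = 5), 0), c("G1", "G2", "G3"))
  expect_identical(alpha_assign(c(G1 = 50), 1), "G1")
  expect_identical(alpha_assign(numeric(0), 0.96), character(0))
  # the arg-max genome always qualifies
  set.seed(81)
  for (i in 1:50) {
    n <- sample(1:6, 1)
    s <- setNames(runif(n, 1, 100), paste0("g", seq_len(n)))
    a <- runif(1)
    expect_true(names(s)[which.max(s)] %in% alpha_assign(s, a))
  }
  expect_error(alpha_assign(c(G1 = 1), 1.5), "alpha")
})

test_that("similarity estimation produces a valid matrix with expected structure", {
  # single genome
  g1 <- generate_genome(2000, seed = 91, id = "g1")
  W1 <- estimate_similarity(g1, read_length = 100, K0 = 50, seed = 92)
  expect_equal(unname(W1$W), matrix(1, 1, 1))

  # independent random genomes: off-diagonals zero after thresholding
  g <- c(g1, generate_genome(2000, seed = 93, id = "g2"))
  W2 <- estimate_similarity(g, read_length = 100, K0 = 200, seed = 94)
  expect_equal(unname(W2$W), diag(2))

  # an exact copy is indistinguishable: w = 1 both ways
  twin <- c(g1, setNames(g1[[1]], "g1copy"))
  W3 <- estimate_similarity(twin, read_length = 100, K0 = 100, seed = 95)
  expect_equal(unname(W3$W), matrix(1, 2, 2))

  # general invariants on a mutant pair
  mut <- mutate_genome(g1, 0.03, seed = 96, id = "g1mut")
  W4 <- estimate_similarity(c(g1, mut), read_length = 100, K0 = 300, seed = 97,
                            alpha = 0.9)
  expect_true(all(W4$W >= 0 & W4$W <= 1))
  expect_equal(unname(diag(W4$W)), c(1, 1))
  off <- W4$W[row(W4$W) != col(W4$W)]
  expect_true(all(off == 0 | off >= W4$threshold))

  # determinism under a fixed seed
  W4b <- estimate_similarity(c(g1, mut), read_length = 100, K0 = 300, seed = 97,
                             alpha = 0.9)
  expect_identical(W4$W, W4b$W)

  # K0 normalization never exceeds the self-normalized variant
  W5 <- estimate_similarity(c(g1, mut), read_length = 100, K0 = 300, seed = 97,
                            alpha = 0.9, normalize = "k0")
  expect_true(all(W5$W <= W4$W + 1e-12))
})

test_that("matrix selection by read length picks the nearest, ties to shorter", {
  mats <- lapply(c(100, 250, 500, 1000), function(rl)
    identity_similarity(c("a", "b"), read_length = rl))
  expect_equal(select_matrix_by_read_length(mats, 110)$read_length, 100)
  expect_equal(select_matrix_by_read_length(mats, 700)$read_length, 500)
  expect_equal(select_matrix_by_read_length(mats[1:2], 175)$read_length, 100)
  expect_equal(select_matrix_by_read_length(mats[3], 80)$read_length, 500)
  expect_error(select_matrix_by_read_length(list(), 100), "available")
})

test_that("matrix restriction takes the principal submatrix in order", {
  set.seed(101)
  M <- random_similarity(4)
  ids <- M$genome_ids

  expect_equal(restrict_matrix(M, ids), M)

  r <- restrict_matrix(M, ids[c(1, 3)])
  expect_identical(r$W, M$W[c(1, 3), c(1, 3)])
  expect_equal(r$read_length, M$read_length)
  expect_equal(r$alpha, M$alpha)

  # requested order is preserved
  r2 <- restrict_matrix(M, ids[c(3, 1)])
  expect_identical(r2$genome_ids, ids[c(3, 1)])
  expect_identical(r2$W, M$W[c(3, 1), c(3, 1)])

  expect_error(restrict_matrix(M, character(0)), "empty")
  expect_error(restrict_matrix(M, "nope"), "nope")
})

test_that("similarity can be assembled from external per-genome hit tables", {
  # source gA: 10 reads, 3 co-assigned to gB at alpha = 0.96
  mk_hits <- function(n, co) {
    rid <- rep(sprintf("r%d", 1:n), times = ifelse(1:n <= co, 2, 1))
    gid <- unlist(lapply(1:n, function(i) if (i <= co) c("gA", "gB") else "gA"))
    sc <- unlist(lapply(1:n, function(i) if (i <= co) c(100, 97) else 100))
    hit_table(rid, gid, sc)
  }
  hbs <- list(gA = mk_hits(10, 3),
              gB = {
                h <- mk_hits(10, 0)
                hit_table(h$read_id, rep("gB", 10), h$score)
              })
  W <- similarity_from_hits(hbs, c("gA", "gB"), read_length = 100, K0 = 10,
                            alpha = 0.96, threshold = 0.001)
  expect_equal(W$W["gA", "gB"], 0.3)
  expect_equal(W$W["gB", "gA"], 0)
  expect_equal(unname(diag(W$W)), c(1, 1))
})
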