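test_that("genome generation is seed-deterministic", {
  g1 <- generate_genome(200, seed = 5)
  g2 <- generate_genome(200, seed = 5)
  g3 <- generate_genome(200, seed = 6)
  expect_identical(g1, g2)
  expect_false(g1[[1]] == g3[[1]])
  expect_equal(nchar(g1[[1]]), 200L)
  expect_error(generate_genome(0), "positive")
})

test_that("mutation applies the per-position substitution model", {
  base <- generate_genome(10000, seed = 21, id = "b")

  expect_identical(mutate_genome(base, 0, seed = 1)[[1]], base[[1]])

  m1 <- mutate_genome(base, 1, seed = 2)
  expect_true(all(strsplit(m1[[1]], "")[[1]] != strsplit(base[[1]], "")[[1]]))

  # rate 0.05 on 10 kb: observed divergence concentrates near the rate
  m <- mutate_genome(base, 0.05, seed = 3)
  d <- mean(strsplit(m[[1]], "")[[1]] != strsplit(base[[1]], "")[[1]])
  expect_gte(d, 0.03)
  expect_lte(d, 0.07)

  expect_error(mutate_genome(base, 1.2), "substitution_rate")
})

test_that("largest-remainder allocation is exact and conserves totals", {
  expect_identical(allocate_counts(c(1, 2) / 3, 100), c(33L, 67L))
  expect_identical(allocate_counts(1, 5), 5L)
  set.seed(31)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1)); p <- p / sum(p)
    total <- sample(10:5000, 1)
    cts <- allocate_counts(p, total)
    expect_equal(sum(cts), total)
    expect_true(all(abs(cts - p * total) < 1))  # each count within 1 of its share
  }
  expect_error(allocate_counts(c(0.5, 0.4), 10), "sum to 1")
})

test_that("read simulation honours counts, positions and the error model", {
  g1 <- generate_genome(500, seed = 41, id = "g1")
  com1 <- synthetic_community(g1, 1, 5, read_length = 50, seed = 42)
  rd1 <- simulate_reads(com1)
  expect_equal(nrow(rd1), 5L)
  expect_true(all(rd1$origin_genome_id == "g1"))
  expect_identical(unname(com1$true_counts), 5L)

  g2 <- generate_genome(500, seed = 43, id = "g2")
  com2 <- synthetic_community(c(g1, g2), c(0.5, 0.5), 4, read_length = 50, seed = 44)
  rd2 <- simulate_reads(com2)
  expect_identical(unname(com2$true_counts), c(2L, 2L))
  # error-free reads are exact substrings of their origin at the recorded start
  for (i in seq_len(nrow(rd2))) {
    origin <- com2$genomes[[rd2$origin_genome_id[i]]]
    expect_identical(rd2$sequence[i],
                     substring(origin, rd2$start[i] + 1, rd2$start[i] + 50))
  }
  expect_true(all(rd2$start + 50 <= nchar(com2$genomes[rd2$origin_genome_id])))

  # read conservation at larger scale
  com3 <- synthetic_community(c(g1, g2), c(1, 2) / 3, 1000, read_length = 50,
                              seed = 45, error_rate = 0.02)
  rd3 <- simulate_reads(com3)
  expect_equal(nrow(rd3), 1000L)
  expect_equal(as.vector(table(rd3$origin_genome_id)[names(com3$genomes)]),
               c(333L, 667L))

  expect_error(synthetic_community(g1, 1, 10, read_length = 1000), "shorter")
  expect_error(synthetic_community(c(g1, g2), c(0.5, 0.4), 10, read_length = 50),
               "sum to 1")
})

test_that("the k-mer aligner scores ungapped alignments correctly", {
  set.seed(51)
  gA <- generate_genome(3000, seed = 52, id = "gA")
  gB <- generate_genome(3000, seed = 53, id = "gB")

  # a perfect 100 bp read from gA hits only gA, scoring match * L
  read <- substring(gA[[1]], 501, 600)
  h <- naive_align(c(r1 = read), c(gA, gB))
  expect_equal(nrow(h), 1L)
  expect_identical(h$genome_id, "gA")
  expect_equal(h$score, 100)

  # identical genomes receive identical scores for every read
  twin <- c(gA, setNames(gA[[1]], "gA2"))
  h2 <- naive_align(c(r1 = read), twin)
  expect_equal(nrow(h2), 2L)
  expect_equal(unique(h2$score), 100)

  # 5 substitutions: score 95 * 1 + 5 * (-2) = 85
  chars <- strsplit(read, "")[[1]]
  pos <- c(30, 45, 60, 75, 90)
  for (p in pos) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
  h3 <- naive_align(c(r1 = paste(chars, collapse = "")), gA)
  expect_equal(h3$score, 85)

  expect_error(naive_align(c(r1 = "ACGT"), gA, k = 16), "seed length")
})

test_that("zero-similarity communities are recovered exactly end to end", {
  g <- c(generate_genome(5000, seed = 61, id = "g1"),
         generate_genome(5000, seed = 62, id = "g2"),
         generate_genome(5000, seed = 63, id = "g3"))
  com <- synthetic_community(g, c(0.5, 0.3, 0.2), 1000, read_length = 100, seed = 64)
  hits <- naive_align(simulate_reads(com), g)
  fit <- taec(hits, identity_similarity(names(g)),
              control = taec_control(n_bootstraps = 20, seed = 65))
  expect_equal(coef(fit, "proportions")[names(g)],
               com$proportions, tolerance = 1e-12)
  expect_equal(unname(coef(fit)[names(g)]), as.numeric(com$true_counts))
})

test_that("estimated similarity decreases with substitution rate", {
  base <- generate_genome(8000, seed = 71, id = "base")
  w_at <- function(rate) {
    mut <- mutate_genome(base, rate, seed = 72, id = "mut")
    W <- estimate_similarity(c(base, mut), read_length = 100, K0 = 400, seed = 73)
    W$W["base", "mut"]
  }
  w_low <- w_at(0.02)
  w_high <- w_at(0.08)
  expect_gt(w_low, w_high)
})
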