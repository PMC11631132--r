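test_that("top hub lists truncate by rank and pool both types", {
  r <- toy_result("MM",
                  seed_genes = c("S1", "S2", "S3"),
                  seed_scores = c(9, 7, 5),
                  int_genes = c("I1", "I2"), int_scores = c(8, 1))
  expect_equal(top_hubs(r, 2, "seed"), c("S1", "S2"))
  expect_equal(top_hubs(r, 10, "seed"), c("S1", "S2", "S3"))
  both <- top_hubs(r, 3, "both")
  expect_equal(both, c("S1", "I1", "S2"))
  expect_length(top_hubs(r, 99, "both"), 5L)
})

test_that("shared hubs count exact top-list membership", {
  mk <- function(cancer, genes) {
    toy_result(cancer, seed_genes = genes,
               seed_scores = rev(seq_along(genes)))
  }
  r1 <- mk("C1", c("G", "A", "B"))
  r2 <- mk("C2", c("G", "C", "D"))
  r3 <- mk("C3", c("G", "A", "E"))
  res <- list(r1, r2, r3)
  at3 <- shared_hubs(res, n = 3, k = 3, gene_type = "seed")
  expect_equal(at3$gene, "G")
  expect_equal(at3$n_cancers, 3L)
  expect_equal(at3$cancers, "C1,C2,C3")
  at2 <- shared_hubs(res, n = 3, k = 2, gene_type = "seed")
  expect_setequal(at2$gene, c("G", "A"))
  expect_equal(at2$gene[1], "G") # sorted by breadth first
  # k = 1 is the union; disjoint lists at k = 2 are empty
  expect_setequal(shared_hubs(res, n = 3, k = 1, gene_type = "seed")$gene,
                  c("G", "A", "B", "C", "D", "E"))
  disjoint <- list(mk("C1", c("A", "B")), mk("C2", c("C", "D")))
  expect_equal(nrow(shared_hubs(disjoint, n = 2, k = 2, "seed")), 0L)
  expect_error(shared_hubs(list(), 3, 1), "empty")
})

test_that("shared hubs shrink as the cancer threshold grows", {
  set.seed(21)
  res <- lapply(1:4, function(i) {
    toy_result(paste0("C", i),
               seed_genes = sample(sprintf("G%02d", 1:15), 8),
               seed_scores = sample(1:20, 8))
  })
  prev <- NULL
  for (k in 1:4) {
    cur <- shared_hubs(res, n = 8, k = k, gene_type = "seed")$gene
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("score matrices assemble with structural zeros and min-max columns", {
  r1 <- toy_result("C1", seed_genes = c("A", "B", "C"),
                   seed_scores = c(0, 5, 10))
  r2 <- toy_result("C2", seed_genes = c("B",  "D"), seed_scores = c(4, 4))
  raw <- build_score_matrix(list(r1, r2), gene_type = "seed",
                            normalize = FALSE)
  expect_equal(dim(raw), c(4L, 2L))
  expect_equal(raw["A", "C2"], 0) # structural zero
  expect_equal(raw["D", "C1"], 0)
  norm <- build_score_matrix(list(r1, r2), gene_type = "seed")
  expect_equal(unname(norm[c("A", "B", "C"), "C1"]), c(0, 0.5, 1))
  # C2 column: scores {0(A), 4(B), 0(C), 4(D)} -> {0, 1, 0, 1}
  expect_equal(unname(norm[, "C2"]), c(0, 1, 0, 1))
  # constant column maps to zeros
  r3 <- toy_result("C3", seed_genes = c("A", "B"), seed_scores = c(3, 3))
  norm3 <- build_score_matrix(list(r3), gene_type = "seed")
  expect_equal(unname(norm3[, 1]), c(0, 0))
})

test_that("min-max normalisation is idempotent and order-preserving", {
  set.seed(4)
  res <- lapply(1:3, function(i) {
    toy_result(paste0("C", i), seed_genes = sprintf("G%02d", 1:10),
               seed_scores = sample(0:30, 10))
  })
  m1 <- build_score_matrix(res, gene_type = "seed")
  expect_true(all(m1 >= 0 & m1 <= 1))
  raw <- build_score_matrix(res, gene_type = "seed", normalize = FALSE)
  for (j in 1:3) {
    expect_equal(order(m1[, j]), order(raw[, j]))
    rng <- range(m1[, j])
    expect_equal(rng, c(0, 1)) # non-constant columns attain both endpoints
    # normalising an already-normalised column is a fixed point
    expect_equal((m1[, j] - min(m1[, j])) / diff(range(m1[, j])), m1[, j])
  }
})

test_that("correlations detect engineered dependence and stay unit-diagonal", {
  n <- 10
  r <- toy_result("C1",
                  seed_genes = sprintf("S%02d", 1:n),
                  seed_scores = 2 * (1:n),
                  seed_M = 2 * (1:n),
                  seed_mut = 1:n,
                  seed_z = stats::rnorm(n) + 3)
  m <- score_correlations(r)
  expect_equal(dim(m), c(3L, 3L))
  expect_equal(unname(diag(m)), c(1, 1, 1))
  expect_equal(m["mutation_count", "network_score"], 1.0)
  expect_equal(m, t(m))
  expect_true(all(m[is.finite(m)] >= -1 & m[is.finite(m)] <= 1))
})

test_that("zero-variance quantities are reported as undefined", {
  r <- toy_result("C1", seed_genes = sprintf("S%02d", 1:5),
                  seed_scores = c(1, 2, 3, 4, 5),
                  seed_mut = rep(2L, 5),
                  seed_z = c(2, 2.5, 3, 3.5, 4))
  expect_warning(m <- score_correlations(r), "zero variance")
  expect_true(all(is.na(m["mutation_count", c("meta_z", "network_score")])))
  expect_equal(m["meta_z", "network_score"], 1.0)
  expect_equal(unname(diag(m)), c(1, 1, 1))
})

test_that("high-score counting uses a strict threshold", {
  r <- toy_result("C1", seed_genes = c("A", "B", "C"),
                  seed_scores = c(50, 101, 150))
  expect_equal(count_high_scores(r, 100), 2L)
  expect_equal(count_high_scores(r, 150), 0L)
  zero <- toy_result("C1", seed_genes = c("A", "B"), seed_scores = c(0, 0))
  expect_equal(count_high_scores(zero, 0), 0L)
  set.seed(3)
  scores <- sample(0:200, 30, replace = TRUE)
  rr <- toy_result("C1", seed_genes = sprintf("S%02d", 1:30),
                   seed_scores = scores)
  expect_equal(count_high_scores(rr, 100), sum(scores > 100))
})

test_that("outliers sit above mean + k sd of the score distribution", {
  r <- toy_result("C1", seed_genes = c("A", "B", "C", "D"),
                  seed_scores = c(1, 1, 1, 10))
  expect_length(detect_outliers(r, 1.96, "seed"), 0L) # cutoff 12.07
  r2 <- toy_result("C1", seed_genes = sprintf("S%d", 1:5),
                   seed_scores = c(0, 0, 0, 0, 100))
  expect_length(detect_outliers(r2, 1.96, "seed"), 0L) # cutoff ~107.6
  expect_equal(detect_outliers(r2, 1, "seed"), "S5")   # cutoff ~64.7
  flat <- toy_result("C1", seed_genes = c("A", "B"), seed_scores = c(3, 3))
  expect_warning(out <- detect_outliers(flat, 1.96, "seed"), "zero")
  expect_length(out, 0L)
})

test_that("outlier sets shrink weakly as the cutoff grows", {
  set.seed(13)
  r <- toy_result("C1", seed_genes = sprintf("S%02d", 1:40),
                  seed_scores = stats::rgeom(40, 0.1))
  prev <- NULL
  for (k in c(0.5, 1, 1.5, 2, 3)) {
    cur <- detect_outliers(r, k, "seed")
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("external overlap is the covered share of the external list", {
  ov <- external_overlap(c("A", "B", "C"),
                         c(sprintf("X%d", 1:7), "A", "B", "C"))
  expect_equal(ov$percentage, 30.0)
  expect_equal(ov$intersection, c("A", "B", "C"))
  expect_equal(external_overlap("A", c("B", "C"))$percentage, 0.0)
  expect_equal(external_overlap(c("A", "B", "C"), c("a", "b"))$percentage,
               100.0)
  expect_error(external_overlap("A", character(0)), "empty external")
})
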