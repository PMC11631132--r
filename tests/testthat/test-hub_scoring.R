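test_that("neighbour counts scan the interaction neighbourhood", {
  star <- interactome(cbind("H", sprintf("X%d", 1:10)))
  nc <- neighbour_counts("H", star, sprintf("X%d", 1:4))
  expect_equal(nc$total_interactors, 10L)
  expect_equal(nc$mutated_interactors, 4L)

  absent <- neighbour_counts("GHOST", star, "X1")
  expect_equal(c(absent$total_interactors, absent$mutated_interactors),
               c(0L, 0L))

  all_mut <- neighbour_counts(c("H", "X1"), star, star$nodes)
  expect_equal(all_mut$mutated_interactors, all_mut$total_interactors)
})

test_that("the network score is the literal product and equals M", {
  expect_equal(network_score(10, 4), 4.0)
  expect_equal(network_score(0, 0), 0.0)
  expect_equal(network_score(5, 5), 5.0)
  expect_equal(network_score(c(10, 0, 5), c(4, 0, 5)), c(4, 0, 5))
  expect_error(network_score(3, 4), "exceeds")
  expect_error(network_score(-1, -1), "negative")
})

make_statuses <- function(genes, counts, types) {
  data.frame(
    gene = genes, cancer = rep("TOY", length(genes)),
    orf_count = as.integer(counts), non_orf_count = rep(0L, length(genes)),
    total_count = as.integer(counts),
    location_class = ifelse(counts > 0, "ORF", "NONE"),
    meta_z = ifelse(types == "seed", 2.7, NA_real_),
    precog_label = ifelse(types == "seed", "oncogene", "none"),
    retained = rep(TRUE, length(genes)),
    cluster = ifelse(types == "seed",
                     ifelse(counts > 0, "MUT_PRECOG", "PRECOG"), "MUT"),
    gene_type = types, stringsAsFactors = FALSE
  )
}

test_that("scoring and ranking match a hand-worked toy graph", {
  # graph: A-B, A-C, A-D, B-C, E-F ; mutated reference = {B, C, F}
  itm <- interactome(rbind(c("A", "B"), c("A", "C"), c("A", "D"),
                           c("B", "C"), c("E", "F")))
  st <- make_statuses(c("A", "B", "E", "D"), c(3, 2, 1, 2),
                      c("seed", "interactor", "seed", "interactor"))
  res <- score_and_rank(st, itm, mutated_set = c("B", "C", "F"),
                        thresholds = filter_thresholds(2, 1))
  # A: T3 M2 -> 2 ; E: T1 M1 -> 1 ; B: T2 M1 -> 1 ; D: T1 M0 -> 0
  expect_equal(res$seeds$gene, c("A", "E"))
  expect_equal(res$seeds$network_score, c(2, 1))
  expect_equal(res$seeds$rank, 1:2)
  expect_equal(res$interactors$gene, c("B", "D"))
  expect_equal(res$interactors$network_score, c(1, 0))
})

test_that("ties break by mutated count then alphabetically", {
  itm <- interactome(rbind(c("Z", "M1"), c("Y", "M1"), c("X", "M1"),
                           c("X", "U1")))
  st <- make_statuses(c("Z", "Y", "X"), c(1, 1, 1),
                      rep("interactor", 3))
  res <- score_and_rank(st, itm, mutated_set = "M1",
                        thresholds = filter_thresholds(1, 1))
  # all scores 1, all M 1 -> alphabetical
  expect_equal(res$interactors$gene, c("X", "Y", "Z"))

  st2 <- make_statuses(c("B", "A"), c(1, 1), rep("interactor", 2))
  itm2 <- interactome(rbind(c("A", "M1"), c("B", "M1"), c("B", "U1"),
                            c("A", "U2"), c("A", "M2")))
  res2 <- score_and_rank(st2, itm2, mutated_set = c("M1", "M2"),
                         thresholds = filter_thresholds(1, 1))
  # A: T3 M2 ; B: T2 M1 -> A first on score
  expect_equal(res2$interactors$gene, c("A", "B"))
})

test_that("empty, duplicate and non-retained inputs are handled", {
  itm <- interactome(rbind(c("A", "B")))
  empty <- score_and_rank(make_statuses(character(0), integer(0), character(0)),
                          itm, thresholds = filter_thresholds(1, 1),
                          cancer = "TOY")
  expect_equal(nrow(empty$seeds), 0L)
  expect_equal(nrow(empty$interactors), 0L)

  dup <- make_statuses(c("A", "A"), c(1, 2), rep("interactor", 2))
  expect_error(score_and_rank(dup, itm, thresholds = filter_thresholds(1, 1)),
               "duplicate")

  bad <- make_statuses("A", 1, "interactor")
  bad$retained <- FALSE
  expect_error(score_and_rank(bad, itm), "non-retained")
})

test_that("scores equal brute-force mutated-neighbour counts on random graphs", {
  for (seed in 1:15) {
    set.seed(seed)
    n <- sample(10:100, 1)
    nodes <- sprintf("N%03d", 1:n)
    g <- igraph::sample_gnp(n, 0.08)
    el <- igraph::as_edgelist(g)
    edges <- cbind(nodes[el[, 1]], nodes[el[, 2]])
    itm <- interactome(edges, nodes = nodes)
    mutated <- sample(nodes, ceiling(n / 3))
    probe <- sample(nodes, 10)
    nc <- neighbour_counts(probe, itm, mutated)
    for (i in seq_along(probe)) {
      want <- oracle_neighbour_counts(edges, nodes, probe[i], mutated)
      expect_equal(nc$total_interactors[i], want[1])
      expect_equal(nc$mutated_interactors[i], want[2])
      expect_equal(network_score(nc$total_interactors[i],
                                 nc$mutated_interactors[i]),
                   as.numeric(want[2]))
    }
  }
})

test_that("ranked lists are a permutation of the retained set", {
  set.seed(99)
  genes <- sprintf("P%02d", 1:20)
  st <- make_statuses(genes, sample(0:5, 20, replace = TRUE),
                      sample(c("seed", "interactor"), 20, replace = TRUE))
  st$cluster[st$total_count == 0 & st$gene_type == "interactor"] <- "MUT"
  st$total_count[st$gene_type == "interactor" & st$total_count == 0] <- 1L
  itm <- interactome(cbind(sample(genes, 30, replace = TRUE),
                           sample(genes, 30, replace = TRUE)))
  res <- score_and_rank(st, itm, thresholds = filter_thresholds(1, 1))
  expect_setequal(c(res$seeds$gene, res$interactors$gene), genes)
  expect_equal(res$seeds$rank, seq_len(nrow(res$seeds)))
  expect_equal(res$interactors$rank, seq_len(nrow(res$interactors)))
  expect_true(all(diff(res$seeds$network_score) <= 0))
  expect_true(all(diff(res$interactors$network_score) <= 0))
})

test_that("adding a mutated neighbour never lowers a score", {
  base_edges <- rbind(c("A", "B"), c("A", "C"), c("D", "B"))
  st <- make_statuses(c("A", "D"), c(1, 1), rep("interactor", 2))
  th <- filter_thresholds(1, 1)
  before <- score_and_rank(st, interactome(base_edges),
                           mutated_set = c("B", "C"), thresholds = th)
  after <- score_and_rank(st, interactome(rbind(base_edges, c("A", "M9"))),
                          mutated_set = c("B", "C", "M9"), thresholds = th)
  sb <- before$interactors
  sa <- after$interactors
  expect_true(sa$network_score[sa$gene == "A"] >
                sb$network_score[sb$gene == "A"])
  expect_equal(sa$network_score[sa$gene == "D"],
               sb$network_score[sb$gene == "D"])
  expect_true(sa$rank[sa$gene == "A"] <= sb$rank[sb$gene == "A"])
})

test_that("scores ignore interactome edge order and mutated-set order", {
  set.seed(5)
  nodes <- sprintf("Q%02d", 1:30)
  edges <- cbind(sample(nodes, 60, replace = TRUE),
                 sample(nodes, 60, replace = TRUE))
  mutated <- sample(nodes, 10)
  st <- make_statuses(nodes[1:8], rep(1, 8), rep("interactor", 8))
  th <- filter_thresholds(1, 1)
  r1 <- score_and_rank(st, interactome(edges), mutated, thresholds = th)
  r2 <- score_and_rank(st, interactome(edges[sample(60), ]),
                       rev(mutated), thresholds = th)
  expect_identical(r1$interactors, r2$interactors)
})
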