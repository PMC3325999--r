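test_that("RF distance is zero on identical trees and matches hand cases", {
  set.seed(31)
  for (n in c(5, 10, 40)) {
    tr <- ape::rtree(n)
    expect_equal(rf_distance(tr, tr), 0)
  }
  # each 5-leaf tree carries two nontrivial splits; none is shared
  t1 <- ape::read.tree(text = "((A,B),(C,D),E);")
  t2 <- ape::read.tree(text = "((A,C),(B,D),E);")
  expect_equal(rf_distance(t1, t2), 4)
  # one shared split: AB occurs in both, the cherry partner differs
  t3 <- ape::read.tree(text = "((A,B),(C,E),D);")
  expect_equal(rf_distance(t1, t3), 2)
  expect_error(rf_distance(t1, ape::read.tree(text = "((A,B),(C,F),E);")),
               "leaf")
})

test_that("max_rf follows 2(n-3) and is achieved by disjoint caterpillars", {
  expect_equal(max_rf(4), 2)
  expect_equal(max_rf(100), 194)
  expect_equal(max_rf(1000), 1994)
  expect_error(max_rf(3), "n_leaves")
  pair <- disjoint_caterpillar_pair(20)
  expect_equal(rf_distance(pair[[1]], pair[[2]]), max_rf(20))
})

test_that("rf_distance never exceeds max_rf on random resolved pairs", {
  set.seed(32)
  for (rep in 1:10) {
    n <- sample(6:30, 1)
    labs <- paste0("t", 1:n)
    t1 <- ape::rtree(n, tip.label = labs)
    t2 <- ape::rtree(n, tip.label = labs)
    expect_lte(rf_distance(t1, t2), max_rf(n))
  }
})

test_that("rf_distance agrees with phangorn and the brute-force oracle", {
  skip_if_not_installed("phangorn")
  set.seed(33)
  for (rep in 1:15) {
    n <- sample(5:25, 1)
    labs <- paste0("t", 1:n)
    t1 <- ape::rtree(n, tip.label = labs)
    t2 <- ape::rtree(n, tip.label = labs)
    expect_equal(rf_distance(t1, t2), brute_force_rf(t1, t2))
    expect_equal(rf_distance(t1, t2),
                 as.integer(phangorn::RF.dist(t1, t2)))
  }
})

test_that("rf_distance is a metric on resolved topologies", {
  set.seed(34)
  labs <- paste0("t", 1:12)
  for (rep in 1:10) {
    ts <- lapply(1:3, function(i) ape::rtree(12, tip.label = labs))
    d12 <- rf_distance(ts[[1]], ts[[2]])
    d13 <- rf_distance(ts[[1]], ts[[3]])
    d23 <- rf_distance(ts[[2]], ts[[3]])
    expect_equal(d12, rf_distance(ts[[2]], ts[[1]]))
    expect_lte(d13, d12 + d23)
  }
})

test_that("consensus marks are 100 on shared branches, 50 otherwise", {
  tr <- generate_tree(16, "balanced")
  same <- consensus_marks(tr, tr)
  expect_true(all(attr(same, "marks")$mark == 100))
  t1 <- ape::read.tree(text = "((A,B),(C,D),E);")
  t2 <- ape::read.tree(text = "((A,C),(B,D),E);")
  m <- attr(consensus_marks(t1, t2), "marks")
  expect_equal(sum(m$mark == 50), 2)   # RF 4 / 2
  # an NNI move flips exactly one bipartition
  skip_if_not_installed("phangorn")
  set.seed(39)
  t10 <- ape::rtree(10)
  nni <- phangorn::rNNI(t10, 1)
  expect_equal(rf_distance(t10, nni), 2)
  m2 <- attr(consensus_marks(t10, nni), "marks")
  expect_equal(sum(m2$mark == 50), 1)
  # 50-mark count is RF/2 for resolved pairs
  labs <- paste0("t", 1:14)
  ta <- ape::rtree(14, tip.label = labs)
  tb <- ape::rtree(14, tip.label = labs)
  expect_equal(2 * sum(attr(consensus_marks(ta, tb), "marks")$mark == 50),
               rf_distance(ta, tb))
})

test_that("deep-node recapitulation is 100 for identical trees and drops
           when deep structure is rearranged", {
  tr <- generate_tree(16, "balanced")
  expect_equal(deep_node_recap(tr, tr), 100)
  # swap two cherries across the root: deep bipartitions change
  est <- tr
  est$tip.label[match(c("t1", "t2", "t9", "t10"), est$tip.label)] <-
    c("t9", "t10", "t1", "t2")
  recap <- deep_node_recap(tr, est)
  expect_lt(recap, 100)
  # brute-force audit: fraction of deep splits of tr present in est
  depths <- phyrn:::min_leaf_depths(tr)
  deep <- which(depths[17:(16 + tr$Nnode)] >= 2)
  splits <- phyrn:::node_bipartitions(tr)[deep]
  est_splits <- brute_force_bipartitions(est)
  manual <- 100 * mean(is.na(splits) | splits %in% est_splits)
  expect_equal(recap, manual)
  expect_error(deep_node_recap(tr, est, min_depth = 99), "deep nodes")
})

test_that("benchmark_run aggregates RF over a seeded grid reproducibly", {
  b1 <- benchmark_run(c(30), replicates = 2,
                      methods = "true_alignment_pdistance_nj",
                      n_taxa = 8, mean_seq_len = 60, isr = 0.03, seed = 4)
  b2 <- benchmark_run(c(30), replicates = 2,
                      methods = "true_alignment_pdistance_nj",
                      n_taxa = 8, mean_seq_len = 60, isr = 0.03, seed = 4)
  expect_identical(b1$results, b2$results)
  expect_equal(unique(b1$summary$n), 2)
  expect_true(all(b1$summary$sd_rf >= 0))
  # mild divergence on a balanced clock tree: recovery is exact
  b0 <- benchmark_run(c(30), replicates = 2,
                      methods = "true_alignment_pdistance_nj",
                      n_taxa = 8, mean_seq_len = 200, isr = 0,
                      topology = "balanced", seed = 5)
  expect_equal(b0$summary$mean_rf, 0)
  expect_error(benchmark_run(numeric(0)), "empty")
})
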