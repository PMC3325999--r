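test_that("generate_tree produces valid ultrametric trees in all modes", {
  for (mode in c("yule", "balanced", "pectinate")) {
    tr <- generate_tree(16, mode, seed = 3)
    expect_s3_class(tr, "phylo")
    expect_equal(length(tr$tip.label), 16)
    expect_equal(anyDuplicated(tr$tip.label), 0)
    expect_true(all(tr$edge.length >= 0))
    expect_true(ape::is.binary(tr))
    depths <- ape::node.depth.edgelength(tr)[1:16]
    expect_equal(depths, rep(1, 16), tolerance = 1e-9)
  }
  expect_error(generate_tree(3, "yule"), "n_taxa")
})

test_that("balanced 4-taxon tree has the symmetric topology", {
  tr <- generate_tree(4, "balanced")
  # ((t1,t2),(t3,t4)): one nontrivial split, a cherry pair
  expect_equal(tree_bipartitions(tr), "t3,t4")
})

test_that("pectinate trees are caterpillars", {
  tr <- generate_tree(8, "pectinate")
  # exactly one internal node has two leaf children
  ntip <- 8
  cherries <- sum(tabulate(tr$edge[tr$edge[, 2] <= ntip, 1]) == 2)
  expect_equal(cherries, 1)
})

test_that("tree generation is deterministic under a fixed seed", {
  t1 <- generate_tree(100, "yule", seed = 1)
  t2 <- generate_tree(100, "yule", seed = 1)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  t3 <- generate_tree(100, "yule", seed = 2)
  expect_false(identical(ape::write.tree(t1), ape::write.tree(t3)))
})

test_that("scale_tree hits the target mean pairwise distance exactly", {
  tr <- generate_tree(4, "balanced")
  s <- scale_tree(tr, 700)
  expect_equal(mean_pairwise_distance(s), 700, tolerance = 1e-9)
  # identity case: rescaling to the current mean changes nothing
  cur <- mean_pairwise_distance(s)
  s2 <- scale_tree(s, cur)
  expect_equal(s2$edge.length, s$edge.length, tolerance = 1e-12)
  # large random tree, recomputed over all 4950 pairs
  big <- scale_tree(generate_tree(100, "yule", seed = 5), 550)
  d <- ape::cophenetic.phylo(big)
  expect_equal(mean(d[lower.tri(d)]), 550, tolerance = 1e-6)
  expect_error(scale_tree(structure(list(edge = matrix(0, 0, 2)),
                                    class = "phylo"), 0),
               "positive")
})

test_that("zero-length trees evolve identical sequences", {
  tr <- generate_tree(5, "pectinate", seed = 1)
  tr$edge.length <- tr$edge.length * 0
  cfg <- sim_config(n_taxa = 5, mean_seq_len = 80, seed = 2)
  fam <- evolve_family(tr, cfg)
  expect_equal(length(unique(fam$sequences)), 1L)
  expect_equal(family_stats(fam)$mean_pairwise_identity, 1.0)
})

test_that("substitution-only mode emits a gapless alignment", {
  cfg <- sim_config(n_taxa = 8, mean_seq_len = 120, mean_pairwise_pam = 300,
                    indel_to_substitution_ratio = 0, seed = 4)
  fam <- simulate_family(cfg)
  expect_false(any(grepl("-", fam$alignment, fixed = TRUE)))
  st <- family_stats(fam)
  expect_equal(st$indel_events_per_position, 0)
  expect_equal(st$avg_gap_length, 0)
  expect_equal(st$isr, 0)
})

test_that("ungapping alignment rows reproduces the leaf sequences", {
  for (seed in 1:3) {
    cfg <- sim_config(n_taxa = 10, mean_seq_len = 150,
                      mean_pairwise_pam = 400,
                      indel_to_substitution_ratio = 0.05, seed = seed)
    fam <- simulate_family(cfg)
    expect_identical(unname(gsub("-", "", fam$alignment, fixed = TRUE)),
                     unname(fam$sequences))
    expect_equal(length(unique(nchar(fam$alignment))), 1L)
    expect_setequal(names(fam$sequences), fam$tree$tip.label)
  }
})

test_that("the same seed reproduces a family byte-for-byte", {
  cfg <- sim_config(n_taxa = 8, mean_seq_len = 100, mean_pairwise_pam = 250,
                    seed = 77)
  f1 <- simulate_family(cfg)
  f2 <- simulate_family(cfg)
  expect_identical(f1$sequences, f2$sequences)
  expect_identical(f1$alignment, f2$alignment)
  expect_identical(f1$events, f2$events)
})

test_that("two-taxon site identity matches the matrix-power expectation", {
  # expected identity = sum_a f_a [P^d]_aa for two leaves at total path d
  for (d in c(150, 500)) {
    tr <- ape::read.tree(text = sprintf("(t1:%g,t2:%g);", d / 2, d / 2))
    ids <- vapply(1:10, function(r) {
      cfg <- sim_config(n_taxa = 4, mean_seq_len = 450,
                        mean_pairwise_pam = d,
                        indel_to_substitution_ratio = 0, seed = 100 * d + r)
      cfg$n_taxa <- 2L
      family_stats(evolve_family(tr, cfg))$mean_pairwise_identity
    }, numeric(1))
    oracle <- pam_expected_identity(d)
    se <- sd(ids) / sqrt(length(ids))
    expect_lt(abs(mean(ids) - oracle), 3 * se + 1e-9)
  }
})

test_that("pairwise identity declines with divergence on average", {
  means <- vapply(c(100, 400, 700), function(pam) {
    mean(vapply(1:10, function(r) {
      cfg <- sim_config(n_taxa = 12, mean_seq_len = 120,
                        mean_pairwise_pam = pam,
                        indel_to_substitution_ratio = 0.03,
                        seed = pam + r)
      family_stats(simulate_family(cfg))$mean_pairwise_identity
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("family_stats counts residue-residue columns and gaps correctly", {
  fam <- structure(list(
    tree = NULL,
    sequences = c(a = "ACDE", b = "ACDF"),
    alignment = c(a = "ACDE-", b = "ACD-F"),
    events = data.frame(branch = c(1L, 2L), type = c("deletion", "deletion"),
                        position = c(4L, 5L), length = c(1L, 1L)),
    n_substitutions = 4L,
    config = NULL), class = "phyrn_family")
  st <- family_stats(fam)
  # columns 4 and 5 are residue-gap, excluded: identity 3/3
  expect_equal(st$mean_pairwise_identity, 1.0)
  expect_equal(st$gap_chars_per_position, 2 / 8)
  expect_equal(st$indel_events_per_position, 2 / 8)
  expect_equal(st$avg_gap_length, 1)
  expect_equal(st$isr, 0.5)
  fam$alignment <- c(a = "", b = "")
  expect_error(family_stats(fam), "empty")
})

test_that("sim_config validates its ranges", {
  expect_error(sim_config(n_taxa = 3), "n_taxa")
  expect_error(sim_config(mean_pairwise_pam = 0), "mean_pairwise_pam")
  expect_error(sim_config(indel_to_substitution_ratio = -1),
               "indel_to_substitution_ratio")
  expect_error(sim_config(indel_length_exponent = 1), "indel_length_exponent")
})
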