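test_that("a single-sequence profile scores its seed residue highest", {
  set.seed(3)
  q <- random_protein(40)
  p <- build_pssm(q)
  expect_equal(p$plen, 40)
  expect_equal(rowSums(p$freqs), rep(1, 40), tolerance = 1e-9)
  expect_equal(sum(p$background), 1, tolerance = 1e-9)
  seed <- phyrn:::aa_encode(q)
  for (i in 1:40) {
    expect_equal(which.max(p$scores[i, ]), seed[i])
  }
})

test_that("pseudocounts vanish in the small-weight limit", {
  # a column where every match carries W: freq(W) -> 1 as weight -> 0
  matches <- matrix(rep(phyrn:::aa_encode("WWWW"), 5), nrow = 5,
                    byrow = TRUE)
  p <- build_pssm("WWWW", matches, pseudocount_weight = 1e-9,
                  weighting = "none")
  expect_equal(p$freqs[1, 18], 1, tolerance = 1e-6)  # W is residue 18
})

test_that("background blending follows the stated pseudocount formula", {
  # column with residues {A:3, G:1}, uniform background, weight 1:
  # freq(A) = (3 + 0.05) / (4 + 1)
  matches <- rbind(phyrn:::aa_encode("A"), phyrn:::aa_encode("A"),
                   phyrn:::aa_encode("A"), phyrn:::aa_encode("G"))
  p <- build_pssm("A", matches, pseudocount_weight = 1,
                  background = rep(0.05, 20), weighting = "none",
                  pseudocount_mode = "background")
  expect_equal(p$freqs[1, 1], (3 + 0.05) / 5, tolerance = 1e-12)
  expect_equal(p$freqs[1, 8], (1 + 0.05) / 5, tolerance = 1e-12)
})

test_that("scores increase with frequency at fixed background", {
  set.seed(4)
  p <- build_pssm(random_protein(30))
  # at a fixed residue (fixed background), score is monotone in frequency
  for (a in c(1, 8, 18)) {
    ord <- order(p$freqs[, a])
    expect_true(all(diff(p$scores[ord, a]) >= 0))
  }
})

test_that("identical database copies of the seed are gathered immediately", {
  set.seed(5)
  s <- random_protein(80)
  db <- setNames(rep(s, 5), paste0("copy", 1:5))
  g <- gather_homologs(s, db, source_id = "seed")
  expect_setequal(g$members, names(db))
  expect_true(g$converged)
  expect_lte(g$iterations, 2L)
})

test_that("an unrelated database gathers nothing beyond the seed", {
  set.seed(6)
  s <- random_protein(60)
  db <- setNames(vapply(1:6, function(i) random_protein(60), character(1)),
                 paste0("r", 1:6))
  g <- gather_homologs(s, db, source_id = "seed")
  expect_length(g$members, 0)
  expect_equal(nrow(g$matches), 1L)
  expect_equal(rownames(g$matches), "seed")
})

test_that("gathered member sets grow monotonically with iteration budget", {
  cfg <- sim_config(n_taxa = 12, mean_seq_len = 100, mean_pairwise_pam = 250,
                    seed = 9)
  fam <- simulate_family(cfg)
  db <- fam$sequences
  sets <- lapply(1:4, function(k) {
    gather_homologs(db[[1]], db, max_iter = k, source_id = "q")$members
  })
  for (k in 1:3) {
    expect_true(all(sets[[k]] %in% sets[[k + 1]]))
  }
})

test_that("build_library yields one profile per query in input order", {
  set.seed(8)
  seqs <- setNames(vapply(1:5, function(i) random_protein(60), character(1)),
                   paste0("s", 1:5))
  lib <- build_library(seqs)
  expect_length(lib$pssms, 5)
  expect_equal(vapply(lib$pssms, `[[`, character(1), "source_id"),
               names(seqs))
  expect_error(build_library(setNames(seqs, rep("dup", 5))), "duplicate")
})

test_that("library construction is deterministic and round-trips bit-exact", {
  cfg <- sim_config(n_taxa = 6, mean_seq_len = 70, mean_pairwise_pam = 150,
                    seed = 10)
  fam <- simulate_family(cfg)
  lib1 <- build_library(fam$sequences)
  lib2 <- build_library(fam$sequences)
  f1 <- tempfile(); f2 <- tempfile(); f3 <- tempfile()
  write_pssm_library(lib1, f1)
  write_pssm_library(lib2, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_pssm_library(f1)
  write_pssm_library(back, f3)
  expect_identical(readLines(f1), readLines(f3))
  expect_equal(back$pssms[[2]]$scores, lib1$pssms[[2]]$scores)
  unlink(c(f1, f2, f3))
})

test_that("non-amino-acid database symbols are rejected", {
  expect_error(gather_homologs("ACDEF", c(x = "ACD3F")), "symbols")
})
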