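test_that("self-alignment of a seed to its own profile is perfect", {
  set.seed(1)
  q <- random_protein(60)
  p <- build_pssm(q, source_id = "q")
  st <- align_to_pssm(q, p)
  expect_equal(st$ids, 60L)
  expect_equal(st$alen, 60L)
  expect_equal(st$aqlen, 60L)
  expect_equal(st$plen, 60L)
  expect_equal(st$gap_chars, 0L)
  expect_equal(product_score(st), 1.0)
})

test_that("an all-negative score matrix yields a no-hit", {
  set.seed(2)
  scores <- matrix(-1, 8, 20)
  p <- toy_pssm(scores, sample.int(20, 8, TRUE))
  expect_null(align_to_pssm(random_protein(10), p))
})

test_that("percent identity, coverage and product score follow the formulas", {
  st <- alignment_stats(ids = 30, alen = 60, aqlen = 45, plen = 90)
  expect_equal(percent_identity(st), 0.5)
  expect_equal(percent_coverage(st), 0.5)
  expect_equal(product_score(st), 0.25)
  d <- arp_gapweight_decomposition(st)
  expect_equal(d$p_arp, 60 / 90)
  expect_equal(d$w_g, 15 / 60)
  expect_equal((1 - d$p_arp) * (1 - d$w_g), 0.25)
  # degenerate corners
  st0 <- alignment_stats(ids = 0, alen = 10, aqlen = 10, plen = 10)
  expect_equal(arp_gapweight_decomposition(st0)$p_arp, 1)
  expect_equal(product_score(st0), 0)
  perfect <- alignment_stats(ids = 20, alen = 20, aqlen = 20, plen = 20)
  expect_equal(product_score(perfect), 1)
  # coverage clamps at 1 when query insertions push aqlen past plen
  clamped <- alignment_stats(ids = 50, alen = 110, aqlen = 100, plen = 90)
  expect_equal(percent_coverage(clamped), 1)
})

test_that("product score equals (1 - p_ARP)(1 - w_g) on random stats", {
  set.seed(42)
  for (i in 1:1000) {
    alen <- sample(2:300, 1)
    aqlen <- sample.int(alen, 1)
    plen <- max(aqlen, sample(2:300, 1))  # unclamped regime
    ids <- sample.int(alen, 1)
    st <- alignment_stats(ids = ids, alen = alen, aqlen = aqlen, plen = plen)
    d <- arp_gapweight_decomposition(st)
    expect_equal(product_score(st), (1 - d$p_arp) * (1 - d$w_g),
                 tolerance = 1e-12)
  }
})

test_that("the aligner matches exhaustive enumeration on small instances", {
  set.seed(7)
  for (qlen in 2:6) {
    for (plen in 2:6) {
      for (rep in 1:3) {
        q <- sample.int(20, qlen, TRUE)
        seed_res <- sample.int(20, plen, TRUE)
        scores <- matrix(round(runif(plen * 20, -4, 4), 2), plen, 20)
        go <- sample(c(2, 5, 11), 1); ge <- 1
        oracle <- brute_force_align(q, scores, seed_res, go, ge)
        r <- phyrn:::cpp_profile_align(q, scores, seed_res, go, ge, TRUE)
        if (oracle$score <= 1e-12) {
          expect_false(isTRUE(r$hit))
        } else {
          expect_true(isTRUE(r$hit))
          expect_equal(r$score, oracle$score, tolerance = 1e-9)
          tuples <- vapply(oracle$stats, paste, character(1), collapse = ":")
          expect_true(paste(c(r$ids, r$alen, r$aqlen), collapse = ":")
                      %in% tuples)
        }
      }
    }
  }
})

test_that("populate_matrix is 0/positive with a dominant diagonal", {
  set.seed(11)
  cfg <- sim_config(n_taxa = 10, mean_seq_len = 90, mean_pairwise_pam = 200,
                    seed = 8)
  fam <- simulate_family(cfg)
  lib <- build_library(fam$sequences)
  pm <- populate_matrix(fam$sequences, lib)
  expect_true(all(pm$values >= 0 & pm$values <= 1))
  expect_equal(pm$row_ids, pm$col_ids)
  for (i in seq_along(pm$row_ids)) {
    expect_true(all(pm$values[i, i] >= pm$values[i, -i]))
  }
})

test_that("matrix entries are invariant under library column permutation", {
  set.seed(12)
  seqs <- setNames(vapply(1:6, function(i) random_protein(70), character(1)),
                   paste0("s", 1:6))
  lib <- build_library(seqs)
  pm <- populate_matrix(seqs, lib)
  perm <- c(4, 2, 6, 1, 3, 5)
  lib2 <- lib
  lib2$pssms <- lib$pssms[perm]
  pm2 <- populate_matrix(seqs, lib2)
  expect_equal(pm2$values, pm$values[, perm])
  expect_equal(pm2$col_ids, pm$col_ids[perm])
})

test_that("invalid alignment stats and inputs are rejected", {
  expect_error(alignment_stats(ids = 5, alen = 4, aqlen = 4, plen = 10),
               "ids")
  expect_error(alignment_stats(ids = 1, alen = 0, aqlen = 0, plen = 10))
  p <- build_pssm("ACDEFGHIK")
  expect_error(align_to_pssm("ACB!", p), "symbols")
  expect_error(align_to_pssm("ACDE", p, gap_open = 0), "positive")
})
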