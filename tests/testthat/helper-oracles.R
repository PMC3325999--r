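# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the aligner oracle enumerates alignments
# directly, and the bipartition oracle walks the raw edge matrix.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(len) paste(sample(AA20, len, TRUE), collapse = "")

# --- brute-force local profile alignment ----------------------------------
# Enumerates every monotone matching between query positions and profile
# positions (a local alignment is fully determined by its matched pairs;
# unmatched residues between consecutive matches cost one affine gap per
# side). Returns the optimal score and the set of stat tuples achieving it.
brute_force_align <- function(q, scores, seed_res, gap_open, gap_extend) {
  n <- length(q); m <- nrow(scores)
  best <- 0
  best_stats <- list()
  gap_cost <- function(k) if (k > 0) gap_open + (k - 1) * gap_extend else 0
  # recursive extension of a matching ending at (i, j)
  extend <- function(i, j, score, ids, alen, aqlen) {
    if (score > best + 1e-12) {
      best <<- score
      best_stats <<- list(c(ids = ids, alen = alen, aqlen = aqlen))
    } else if (abs(score - best) <= 1e-12 && best > 0) {
      best_stats[[length(best_stats) + 1L]] <<-
        c(ids = ids, alen = alen, aqlen = aqlen)
    }
    if (i < n && j < m) {
      for (i2 in (i + 1):n) {
        for (j2 in (j + 1):m) {
          a <- i2 - i - 1L   # unmatched query residues (profile-gap columns)
          b <- j2 - j - 1L   # unmatched profile positions (query-gap columns)
          extend(i2, j2,
                 score + scores[j2, q[i2]] - gap_cost(a) - gap_cost(b),
                 ids + (q[i2] == seed_res[j2]),
                 alen + 1L + a + b, aqlen + 1L + a)
        }
      }
    }
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      extend(i, j, scores[j, q[i]], as.integer(q[i] == seed_res[j]), 1L, 1L)
    }
  }
  list(score = best, stats = unique(best_stats))
}

# --- bipartitions straight from the edge matrix ---------------------------
# For every internal edge, collect the tips on the child side by walking the
# edge list; canonicalize as in the package but computed independently.
brute_force_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1]
  edge <- tree$edge
  out <- character(0)
  internal <- edge[, 2] > ntip
  for (k in which(internal)) {
    # BFS from the child node over child edges
    stack <- edge[k, 2]
    tips <- integer(0)
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      kids <- edge[edge[, 1] == v, 2]
      tips <- c(tips, kids[kids <= ntip])
      stack <- c(stack, kids[kids > ntip])
    }
    side <- tree$tip.label[tips]
    other <- setdiff(tree$tip.label, side)
    if (length(side) < 2L || length(other) < 2L) next
    if (ref %in% side) side <- other
    out <- c(out, paste(sort(side), collapse = ","))
  }
  unique(out)
}

brute_force_rf <- function(t1, t2) {
  b1 <- brute_force_bipartitions(t1)
  b2 <- brute_force_bipartitions(t2)
  sum(!(b1 %in% b2)) + sum(!(b2 %in% b1))
}

# caterpillar tree over the given leaf order (unit branch lengths)
caterpillar <- function(labels) {
  nwk <- paste0("(", labels[1], ":1,", labels[2], ":1)")
  for (i in 3:length(labels)) nwk <- paste0("(", nwk, ":1,", labels[i], ":1)")
  ape::read.tree(text = paste0(nwk, ";"))
}

# two caterpillars sharing no nontrivial bipartition: natural leaf order
# versus odds-then-evens (prefix sets of one are never prefix sets of the
# other for n >= 6)
disjoint_caterpillar_pair <- function(n) {
  labs <- paste0("t", seq_len(n))
  list(caterpillar(labs),
       caterpillar(labs[c(seq(1, n, 2), seq(2, n, 2))]))
}

# random PSSM-like object with hand-set scores, for engineered aligner cases
toy_pssm <- function(scores, seed_res) {
  structure(list(source_id = "toy", seed = seed_res, plen = nrow(scores),
                 scores = scores, freqs = NULL,
                 background = rep(0.05, 20), params = list()),
            class = "phyrn_pssm")
}
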