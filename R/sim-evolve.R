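#' Simulation configuration
#'
#' Bundles and validates the parameters of one simulated protein family.
#'
#' @param n_taxa Number of leaves (>= 4).
#' @param mean_seq_len Root sequence length in residues (default 450).
#' @param mean_pairwise_pam Target mean pairwise leaf divergence in PAM
#'   units (the divergence dial; the benchmark sweeps roughly 100-700).
#' @param indel_to_substitution_ratio Expected indel events per expected
#'   substitution on each branch; 0 disables indels entirely
#'   (substitution-only mode).
#' @param indel_length_exponent Zipf exponent (> 1) of the indel length law.
#' @param max_indel_length Truncation point of the indel length law.
#' @param topology_mode Tree shape passed to [generate_tree()].
#' @param seed Integer seed making the whole replicate reproducible.
#' @return A validated list of class `phyrn_sim_config`.
#' @export
sim_config <- function(n_taxa = 100L, mean_seq_len = 450L,
                       mean_pairwise_pam = 550,
                       indel_to_substitution_ratio = 0.03,
                       indel_length_exponent = 1.7,
                       max_indel_length = 40L,
                       topology_mode = c("yule", "balanced", "pectinate"),
                       seed = 1L) {
  topology_mode <- match.arg(topology_mode)
  chk <- function(x, name, lo, int = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo ||
        (int && x != round(x))) {
      stop(name, " must be a single ", if (int) "integer " else "number ",
           ">= ", lo, call. = FALSE)
    }
  }
  chk(n_taxa, "n_taxa", 4, int = TRUE)
  chk(mean_seq_len, "mean_seq_len", 1, int = TRUE)
  chk(mean_pairwise_pam, "mean_pairwise_pam", .Machine$double.eps)
  chk(indel_to_substitution_ratio, "indel_to_substitution_ratio", 0)
  chk(indel_length_exponent, "indel_length_exponent", 1 + 1e-9)
  chk(max_indel_length, "max_indel_length", 1, int = TRUE)
  structure(list(n_taxa = as.integer(n_taxa),
                 mean_seq_len = as.integer(mean_seq_len),
                 mean_pairwise_pam = mean_pairwise_pam,
                 indel_to_substitution_ratio = indel_to_substitution_ratio,
                 indel_length_exponent = indel_length_exponent,
                 max_indel_length = as.integer(max_indel_length),
                 topology_mode = topology_mode,
                 seed = as.integer(seed)),
            class = "phyrn_sim_config")
}

# truncated Zipf sampler: P(k) proportional to k^-s, k = 1..kmax
rzipf_trunc <- function(n, s, kmax) {
  p <- (1:kmax)^(-s)
  sample.int(kmax, n, replace = TRUE, prob = p)
}

#' Evolve a protein family along a tree
#'
#' Places a random root sequence (i.i.d. from the Dayhoff equilibrium
#' frequencies) at the root and evolves it down every branch. Along a branch
#' of length `d` PAM each site is resampled from the corresponding row of the
#' Dayhoff transition matrix at distance `round(d)`; indel events are then
#' laid down as a Poisson count with mean
#' `indel_to_substitution_ratio * (d/100) * L`, each an insertion or deletion
#' with probability 1/2 and truncated-Zipf length. Because every surviving
#' site carries a persistent coordinate key, the true multiple alignment of
#' the leaves is emitted alongside the sequences.
#'
#' @param tree A rooted `phylo` tree with branch lengths in PAM units
#'   (typically [generate_tree()] then [scale_tree()]).
#' @param config A [sim_config()] object; its `n_taxa` must match the tree.
#' @return An object of class `phyrn_family`: list with `tree`, `sequences`
#'   (named character), `alignment` (named character, `-` gaps, equal
#'   lengths), `events` (data.frame: branch, type, position, length),
#'   `n_substitutions`, and `config`.
#' @export
evolve_family <- function(tree, config) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "phyrn_sim_config"))
  if (length(tree$tip.label) != config$n_taxa) {
    stop("tree has ", length(tree$tip.label), " leaves but config$n_taxa is ",
         config$n_taxa, call. = FALSE)
  }
  withr::with_seed(derive_seed(config$seed, 1L), {
    evolve_family_impl(tree, config)
  })
}

evolve_family_impl <- function(tree, config) {
  bf <- dayhoff_frequencies()
  L0 <- config$mean_seq_len
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  root_res <- sample.int(20, L0, replace = TRUE, prob = bf)
  root_keys <- as.numeric(seq_len(L0))

  states <- vector("list", ntip + tree$Nnode)
  states[[root]] <- list(keys = root_keys, res = root_res)

  ev_branch <- integer(0); ev_type <- character(0)
  ev_pos <- integer(0); ev_len <- integer(0)
  n_sub <- 0L

  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  elen <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (k in seq_len(nrow(edges))) {
    par <- edges[k, 1]; ch <- edges[k, 2]
    st <- states[[par]]
    keys <- st$keys; res <- st$res
    d <- round(elen[k])
    L <- length(res)
    if (d > 0 && L > 0) {
      P <- pam_matrix(d)
      new_res <- res
      for (a in unique(res)) {
        idx <- which(res == a)
        new_res[idx] <- sample.int(20, length(idx), replace = TRUE,
                                   prob = P[a, ])
      }
      n_sub <- n_sub + sum(new_res != res)
      res <- new_res
      # indel events after substitutions on this branch
      lam <- config$indel_to_substitution_ratio * (d / 100) * L
      n_ev <- if (lam > 0) rpois(1, lam) else 0L
      if (n_ev > 0) {
        for (e in seq_len(n_ev)) {
          L <- length(res)
          if (L == 0L) break
          type <- if (runif(1) < 0.5) "insertion" else "deletion"
          len <- rzipf_trunc(1, config$indel_length_exponent,
                             config$max_indel_length)
          if (type == "insertion") {
            pos <- sample.int(L + 1L, 1L) - 1L   # insert after site `pos`
            lo <- if (pos == 0L) keys[1] - 1 else keys[pos]
            hi <- if (pos == L) keys[L] + 1 else keys[pos + 1L]
            newk <- lo + (hi - lo) * sort(runif(len))
            newr <- sample.int(20, len, replace = TRUE, prob = bf)
            keys <- append(keys, newk, after = pos)
            res <- append(res, newr, after = pos)
          } else {
            len <- min(len, L)
            pos <- sample.int(L - len + 1L, 1L)
            drop <- pos:(pos + len - 1L)
            keys <- keys[-drop]
            res <- res[-drop]
          }
          ev_branch <- c(ev_branch, ch); ev_type <- c(ev_type, type)
          ev_pos <- c(ev_pos, as.integer(pos)); ev_len <- c(ev_len, len)
        }
      }
    }
    states[[ch]] <- list(keys = keys, res = res)
  }

  # assemble leaf sequences and the true alignment from site keys
  leaf_states <- states[seq_len(ntip)]
  all_keys <- sort(unique(unlist(lapply(leaf_states, `[[`, "keys"))))
  aln <- vapply(leaf_states, function(st) {
    row <- rep("-", length(all_keys))
    row[match(st$keys, all_keys)] <- AA_ALPHABET[st$res]
    paste(row, collapse = "")
  }, character(1))
  seqs <- vapply(leaf_states, function(st) aa_decode(st$res), character(1))
  names(aln) <- names(seqs) <- tree$tip.label

  structure(list(tree = tree,
                 sequences = seqs,
                 alignment = aln,
                 events = data.frame(branch = ev_branch, type = ev_type,
                                     position = ev_pos, length = ev_len,
                                     stringsAsFactors = FALSE),
                 n_substitutions = n_sub,
                 config = config),
            class = "phyrn_family")
}

#' Simulate one complete family
#'
#' Convenience wrapper: generate an ultrametric tree, scale it to the target
#' divergence, and evolve sequences along it, all from one config.
#'
#' @param config A [sim_config()] object.
#' @return A `phyrn_family` (see [evolve_family()]).
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "phyrn_sim_config"))
  tr <- generate_tree(config$n_taxa, config$topology_mode,
                      seed = derive_seed(config$seed, 0L))
  tr <- scale_tree(tr, config$mean_pairwise_pam)
  evolve_family(tr, config)
}

# alignment rows as an integer matrix, 0 = gap
alignment_int_matrix <- function(alignment) {
  rows <- lapply(alignment, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    x <- match(ch, AA_ALPHABET)
    x[ch == "-"] <- 0L
    x[is.na(x)] <- 0L
    x
  })
  if (length(unique(lengths(rows))) != 1L) {
    stop("alignment rows differ in length", call. = FALSE)
  }
  do.call(rbind, rows)
}

#' Divergence statistics of a simulated family
#'
#' Computes, from the true alignment and event log:
#' \describe{
#'   \item{mean_pairwise_identity}{identical residues / residue-residue
#'     columns, averaged over all unordered leaf pairs (gap columns are
#'     excluded pair by pair).}
#'   \item{indel_events_per_position}{logged indel events divided by the
#'     total residue count over all leaves.}
#'   \item{gap_chars_per_position}{gap characters in the alignment divided
#'     by the same residue total.}
#'   \item{avg_gap_length}{mean logged indel event length (0 when no event
#'     occurred).}
#'   \item{isr}{realized indel events / realized substitutions.}
#' }
#'
#' @param family A `phyrn_family`.
#' @return A list of class `phyrn_divergence_stats`.
#' @export
family_stats <- function(family) {
  stopifnot(inherits(family, "phyrn_family"))
  if (length(family$alignment) == 0L || all(nchar(family$alignment) == 0L)) {
    stop("family has an empty alignment", call. = FALSE)
  }
  M <- alignment_int_matrix(family$alignment)
  pid <- cpp_pairwise_identity(M)
  mpi <- mean(pid[lower.tri(pid)], na.rm = TRUE)
  total_res <- sum(M > 0L)
  n_ev <- nrow(family$events)
  stats <- list(
    mean_pairwise_identity = mpi,
    indel_events_per_position = n_ev / total_res,
    gap_chars_per_position = sum(M == 0L) / total_res,
    avg_gap_length = if (n_ev > 0) mean(family$events$length) else 0,
    isr = if (family$n_substitutions > 0) n_ev / family$n_substitutions else 0
  )
  structure(stats, class = "phyrn_divergence_stats")
}

#' @export
print.phyrn_divergence_stats <- function(x, ...) {
  cat("Divergence statistics:\n")
  cat(sprintf("  mean pairwise identity   : %.4f (%.2f%%)\n",
              x$mean_pairwise_identity, 100 * x$mean_pairwise_identity))
  cat(sprintf("  indel events / position  : %.4f\n",
              x$indel_events_per_position))
  cat(sprintf("  gap chars / position     : %.4f\n",
              x$gap_chars_per_position))
  cat(sprintf("  average gap length       : %.2f\n", x$avg_gap_length))
  cat(sprintf("  indel/substitution ratio : %.4f\n", x$isr))
  invisible(x)
}
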