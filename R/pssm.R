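#' Build a position-specific scoring matrix from gathered matches
#'
#' Constructs a profile over the seed's coordinates. Per position, observed
#' residue frequencies among the matches (sequence-weighted, gaps excluded)
#' are blended with a pseudocount distribution via a single weight:
#' `freq = (weighted_count + w * pseudo) / (weighted_total + w)`, and scores
#' are half-bit log-odds `2 * log2(freq / background)`. With no matches the
#' result is the single-sequence profile of the seed (not an error).
#'
#' @param seed_seq Seed protein sequence; `plen` equals its length.
#' @param matches Optional integer matrix (rows = gathered members, columns
#'   = seed positions; entries 1..20 residues, 0 = gap/uncovered), typically
#'   from [gather_homologs()]. The seed itself should be one of the rows.
#' @param pseudocount_weight Positive pseudocount mass per column (default
#'   10, the conventional PSI-BLAST magnitude; light columns then lean on
#'   the substitution prior, which keeps profile searches sensitive and
#'   distant alignments long).
#' @param background Residue background frequencies (default Dayhoff
#'   equilibrium).
#' @param weighting `"henikoff"` (position-based sequence weighting, the
#'   default; prevents stacks of near-identical members from dominating) or
#'   `"none"`.
#' @param pseudocount_mode `"substitution"` (default): pseudocounts follow
#'   the Dayhoff conditional distribution of the observed residues
#'   (`pseudo(a) = sum_b obs(b) P250[b, a]`), so a sparse column still gives
#'   chemically similar residues positive scores — a single-sequence profile
#'   then behaves like a classical PAM substitution matrix, which is what
#'   lets iterative gathering detect twilight-zone relatives.
#'   `"background"`: plain background-proportional pseudocounts.
#' @param source_id Identifier of the seed query.
#' @return An object of class `phyrn_pssm` with fields `source_id`, `seed`
#'   (integer-encoded), `plen`, `scores` and `freqs` (`plen` x 20), and
#'   `background`.
#' @export
build_pssm <- function(seed_seq, matches = NULL, pseudocount_weight = 10,
                       background = dayhoff_frequencies(),
                       weighting = c("henikoff", "none"),
                       pseudocount_mode = c("substitution", "background"),
                       source_id = "seed") {
  weighting <- match.arg(weighting)
  pseudocount_mode <- match.arg(pseudocount_mode)
  if (pseudocount_weight <= 0) {
    stop("pseudocount_weight must be positive", call. = FALSE)
  }
  seed <- aa_encode(seed_seq)
  plen <- length(seed)
  background <- background / sum(background)
  if (is.null(matches) || NROW(matches) == 0L) {
    matches <- matrix(seed, nrow = 1L)
  }
  if (ncol(matches) != plen) {
    stop("matches must have one column per seed position", call. = FALSE)
  }
  w <- if (weighting == "henikoff") henikoff_weights(matches)
       else rep(1, nrow(matches))
  counts <- matrix(0, plen, 20)
  for (i in seq_len(nrow(matches))) {
    idx <- which(matches[i, ] > 0L)
    if (length(idx)) {
      counts[cbind(idx, matches[i, idx])] <-
        counts[cbind(idx, matches[i, idx])] + w[i]
    }
  }
  wtot <- rowSums(counts)
  pseudo <- if (pseudocount_mode == "substitution") {
    obs <- counts / ifelse(wtot > 0, wtot, 1)
    obs %*% pam_matrix(250)   # Dayhoff-conditional pseudocount distribution
  } else {
    matrix(background, plen, 20, byrow = TRUE)
  }
  freqs <- (counts + pseudocount_weight * pseudo) /
    (wtot + pseudocount_weight)
  dimnames(freqs) <- NULL
  # half-bit log-odds, the scale on which the BLAST 11/1 gap convention sits
  scores <- 2 * log2(freqs / matrix(background, plen, 20, byrow = TRUE))
  structure(list(source_id = source_id, seed = seed, plen = plen,
                 scores = scores, freqs = freqs, background = background,
                 params = list(pseudocount_weight = pseudocount_weight,
                               weighting = weighting,
                               pseudocount_mode = pseudocount_mode,
                               n_matches = nrow(matches))),
            class = "phyrn_pssm")
}

# Henikoff & Henikoff position-based sequence weights, normalized to sum to
# the number of sequences (so unweighted counting is recovered when all rows
# are interchangeable)
henikoff_weights <- function(matches) {
  n <- nrow(matches)
  w <- numeric(n)
  for (p in seq_len(ncol(matches))) {
    col <- matches[, p]
    res <- col[col > 0L]
    if (!length(res)) next
    tab <- tabulate(res, 20L)
    r <- sum(tab > 0L)
    idx <- which(col > 0L)
    w[idx] <- w[idx] + 1 / (r * tab[col[idx]])
  }
  if (sum(w) == 0) return(rep(1, n))
  w * (n / sum(w))
}

# Extreme-value calibration of raw local-alignment scores: align a few
# single-sequence profiles against residue-shuffled database sequences and
# fit a Gumbel law by the method of moments. E-values are then
# n_db * exp(-lambda * (S - mu)), the expected number of database sequences
# reaching score S by chance. Estimated once per library build.
estimate_evalue_params <- function(queries_enc, db_enc, gap_open, gap_extend,
                                   n_profiles = 3L, n_shuffles = 30L) {
  withr::with_seed(20111206L, {
    use <- queries_enc[seq_len(min(n_profiles, length(queries_enc)))]
    pool <- db_enc[sample.int(length(db_enc),
                              min(n_shuffles, length(db_enc) * 3L),
                              replace = TRUE)]
    shuffled <- lapply(pool, sample)
    scores <- numeric(0)
    for (q in use) {
      prof <- build_pssm(aa_decode(q))
      for (s in shuffled) {
        r <- cpp_profile_align(s, prof$scores, prof$seed, gap_open,
                               gap_extend, FALSE)
        scores <- c(scores, r$score)
      }
    }
    sdv <- sd(scores)
    if (!is.finite(sdv) || sdv <= 0) sdv <- 1
    lambda <- pi / (sdv * sqrt(6))
    mu <- mean(scores) - 0.5772156649 / lambda
    list(lambda = lambda, mu = mu)
  })
}

evalue_from_score <- function(score, calib, n_db) {
  n_db * exp(-calib$lambda * (score - calib$mu))
}

# project a traceback alignment onto seed coordinates: integer vector of
# length plen, 0 where the member leaves the position uncovered or gapped
match_row_from_traceback <- function(r, member_enc, plen) {
  row <- integer(plen)
  keep <- r$ppos > 0L & r$qpos > 0L
  row[r$ppos[keep]] <- member_enc[r$qpos[keep]]
  row
}

#' Iteratively gather homologs of a seed sequence
#'
#' Profile search in the style of iterative PSI-BLAST gathering: iteration 1
#' searches the database with the seed's single-sequence profile; each later
#' iteration rebuilds the profile from all members gathered so far (aligned
#' to seed coordinates) and searches again. Members accumulate, so the
#' gathered set is non-decreasing across iterations; the loop stops when an
#' iteration adds no new member or after `max_iter` iterations.
#'
#' @param seed_seq Seed protein sequence.
#' @param db Named character vector of database sequences (may include the
#'   seed itself).
#' @param max_iter Maximum profile iterations (default 6).
#' @param evalue_cut Inclusion e-value threshold (default 1e-6).
#' @param gap_open,gap_extend Affine gap penalties.
#' @param pseudocount_weight,weighting Passed to [build_pssm()].
#' @param calib Optional precomputed e-value calibration (from a library
#'   build); when `NULL` it is estimated from shuffled database sequences.
#' @param source_id Identifier recorded on the resulting profile.
#' @return List with `members` (ids of gathered database sequences),
#'   `matches` (integer matrix in seed coordinates, seed row first),
#'   `iterations`, `converged`.
#' @export
gather_homologs <- function(seed_seq, db, max_iter = 6L, evalue_cut = 1e-6,
                            gap_open = 11, gap_extend = 1,
                            pseudocount_weight = 10,
                            weighting = "henikoff", calib = NULL,
                            source_id = "seed") {
  db <- validate_seqs(db)
  db_enc <- lapply(db, aa_encode)
  seed_enc <- aa_encode(seed_seq)
  if (is.null(calib)) {
    calib <- estimate_evalue_params(list(seed_enc), db_enc, gap_open,
                                    gap_extend, n_profiles = 1L)
  }
  plen <- length(seed_enc)
  members <- character(0)
  matches <- matrix(seed_enc, nrow = 1L,
                    dimnames = list(source_id, NULL))
  prof <- build_pssm(seed_seq, matches, pseudocount_weight,
                     weighting = weighting, source_id = source_id)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    hits <- character(0)
    tracebacks <- list()
    for (id in names(db)) {
      r <- cpp_profile_align(db_enc[[id]], prof$scores, prof$seed,
                             gap_open, gap_extend, TRUE)
      if (!isTRUE(r$hit)) next
      ev <- evalue_from_score(r$score, calib, length(db))
      if (ev <= evalue_cut) {
        hits <- c(hits, id)
        tracebacks[[id]] <- r
      }
    }
    new_members <- setdiff(hits, members)
    members <- union(members, hits)
    if (length(new_members) == 0L) {
      converged <- TRUE
      break
    }
    rows <- lapply(members, function(id) {
      r <- tracebacks[[id]]
      if (is.null(r)) {   # carried over from an earlier iteration: realign
        r <- cpp_profile_align(db_enc[[id]], prof$scores, prof$seed,
                               gap_open, gap_extend, TRUE)
        if (!isTRUE(r$hit)) return(integer(plen))
      }
      match_row_from_traceback(r, db_enc[[id]], plen)
    })
    matches <- rbind(matrix(seed_enc, nrow = 1L), do.call(rbind, rows))
    rownames(matches) <- c(source_id, members)
    prof <- build_pssm(seed_seq, matches, pseudocount_weight,
                       weighting = weighting, source_id = source_id)
  }
  list(members = members, matches = matches, iterations = iter,
       converged = converged, calib = calib)
}

#' Build a PSSM library from a query set
#'
#' One profile per query, gathered from `db` (which defaults to the query
#' set itself: simulated families have no outside homologs, so the family is
#' its own gathering database; supply an external sequence set to enrich
#' profiles). Library order follows query order and defines the column order
#' of the product-score matrix. Construction is deterministic given
#' `(queries, db, params)`.
#'
#' @param queries Named character vector of query sequences (unique ids).
#' @param db Gathering database; defaults to `queries`.
#' @param max_iter,evalue_cut,gap_open,gap_extend,pseudocount_weight,weighting
#'   Passed to [gather_homologs()] / [build_pssm()].
#' @param verbose Print per-query progress.
#' @return An object of class `phyrn_pssm_library`: list with `pssms` (list
#'   of `phyrn_pssm`) and `metadata`.
#' @export
build_library <- function(queries, db = queries, max_iter = 6L,
                          evalue_cut = 1e-6, gap_open = 11, gap_extend = 1,
                          pseudocount_weight = 10, weighting = "henikoff",
                          verbose = FALSE) {
  queries <- validate_seqs(queries)
  db <- validate_seqs(db)
  queries_enc <- lapply(queries, aa_encode)
  db_enc <- lapply(db, aa_encode)
  calib <- estimate_evalue_params(queries_enc, db_enc, gap_open, gap_extend)
  pssms <- vector("list", length(queries))
  for (i in seq_along(queries)) {
    id <- names(queries)[i]
    g <- gather_homologs(queries[[i]], db, max_iter = max_iter,
                         evalue_cut = evalue_cut, gap_open = gap_open,
                         gap_extend = gap_extend,
                         pseudocount_weight = pseudocount_weight,
                         weighting = weighting, calib = calib,
                         source_id = id)
    pssms[[i]] <- build_pssm(queries[[i]], g$matches, pseudocount_weight,
                             weighting = weighting, source_id = id)
    if (verbose) {
      message(sprintf("profile %s: %d members, %d iterations", id,
                      length(g$members), g$iterations))
    }
  }
  structure(list(pssms = pssms,
                 metadata = list(
                   n_pssms = length(pssms),
                   db_fingerprint = seqset_fingerprint(db),
                   params = list(max_iter = max_iter,
                                 evalue_cut = evalue_cut,
                                 gap_open = gap_open,
                                 gap_extend = gap_extend,
                                 pseudocount_weight = pseudocount_weight,
                                 weighting = weighting))),
            class = "phyrn_pssm_library")
}

# deterministic fingerprint of a named sequence set
seqset_fingerprint <- function(seqs) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste0(names(seqs), ":", unname(seqs)), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.phyrn_pssm <- function(x, ...) {
  cat(sprintf("PSSM '%s': %d positions, built from %d match(es)\n",
              x$source_id, x$plen, x$params$n_matches))
  invisible(x)
}

#' @export
print.phyrn_pssm_library <- function(x, ...) {
  cat(sprintf("PSSM library: %d profiles (db fingerprint %s)\n",
              length(x$pssms), substr(x$metadata$db_fingerprint, 1, 8)))
  invisible(x)
}
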