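#' Alignment statistics
#'
#' Container for the counts of one query-versus-PSSM local alignment, the
#' inputs of the product score: `ids` (identical residues), `alen` (alignment
#' length including gaps), `aqlen` (alignment length in the query excluding
#' gaps), `plen` (PSSM length), `gap_chars` (= `alen - aqlen`), `raw_score`,
#' and optionally `evalue`.
#'
#' @param ids,alen,aqlen,plen,raw_score,evalue See description.
#' @return A validated list of class `phyrn_alignment_stats`.
#' @export
alignment_stats <- function(ids, alen, aqlen, plen, raw_score = NA_real_,
                            evalue = NA_real_) {
  ids <- as.integer(ids); alen <- as.integer(alen)
  aqlen <- as.integer(aqlen); plen <- as.integer(plen)
  if (alen <= 0 || aqlen <= 0 || plen <= 0) {
    stop("alen, aqlen and plen must be positive", call. = FALSE)
  }
  if (ids < 0 || ids > alen || aqlen > alen) {
    stop("require 0 <= ids <= alen and 0 < aqlen <= alen", call. = FALSE)
  }
  structure(list(ids = ids, alen = alen, aqlen = aqlen, plen = plen,
                 gap_chars = alen - aqlen, raw_score = raw_score,
                 evalue = evalue),
            class = "phyrn_alignment_stats")
}

#' Align a query sequence to a PSSM
#'
#' Best local (Smith-Waterman, affine-gap) alignment of the query against
#' the per-position score rows of the profile. A residue counts as
#' "identical" when the query letter equals the profile's seed letter at the
#' aligned position. Returns `NULL` when no positive-scoring local alignment
#' exists (a no-hit).
#'
#' @param query Protein sequence (character scalar, 20-letter alphabet).
#' @param pssm A `phyrn_pssm` from [build_pssm()].
#' @param gap_open,gap_extend Positive affine gap penalties in score (bit)
#'   units; defaults 11 and 1.
#' @return A [alignment_stats()] object, or `NULL` for no-hit.
#' @export
align_to_pssm <- function(query, pssm, gap_open = 11, gap_extend = 1) {
  stopifnot(inherits(pssm, "phyrn_pssm"))
  if (!is.character(query) || length(query) != 1L || nchar(query) == 0L) {
    stop("query must be a nonempty protein sequence", call. = FALSE)
  }
  if (gap_open <= 0 || gap_extend <= 0) {
    stop("gap penalties must be positive", call. = FALSE)
  }
  q <- aa_encode(query)
  r <- cpp_profile_align(q, pssm$scores, pssm$seed, gap_open, gap_extend,
                         TRUE)
  if (!isTRUE(r$hit)) return(NULL)
  alignment_stats(ids = r$ids, alen = r$alen, aqlen = r$aqlen,
                  plen = pssm$plen, raw_score = r$score)
}

#' Percent identity of an alignment
#'
#' Identical residues divided by alignment length including gaps, as a
#' fraction in `[0, 1]`.
#'
#' @param stats A `phyrn_alignment_stats`.
#' @return `ids / alen`.
#' @export
percent_identity <- function(stats) {
  stopifnot(inherits(stats, "phyrn_alignment_stats"))
  if (stats$alen <= 0) stop("alen must be positive", call. = FALSE)
  stats$ids / stats$alen
}

#' Percent coverage of an alignment
#'
#' Query-resident alignment length divided by profile length, clamped to 1
#' when query insertions push `aqlen` past `plen` (keeps the product score
#' inside `[0, 1]`).
#'
#' @param stats A `phyrn_alignment_stats`.
#' @return `min(1, aqlen / plen)`.
#' @export
percent_coverage <- function(stats) {
  stopifnot(inherits(stats, "phyrn_alignment_stats"))
  if (stats$plen <= 0) stop("plen must be positive", call. = FALSE)
  min(1, stats$aqlen / stats$plen)
}

#' Product score of an alignment
#'
#' The per-(query, PSSM) statistic: percent identity times percent coverage,
#' a fraction in `[0, 1]`. Algebraically equal to
#' `(1 - p_ARP) * (1 - w_g)` (see [arp_gapweight_decomposition()]) whenever
#' coverage is not clamped.
#'
#' @param stats A `phyrn_alignment_stats`.
#' @return Product score in `[0, 1]`.
#' @export
product_score <- function(stats) {
  percent_identity(stats) * percent_coverage(stats)
}

#' Alignment-restricted p-distance and gap-weight decomposition
#'
#' Decomposes the product score into its two interpretable parts: the
#' alignment-restricted p-distance `p_ARP = (plen - ids) / plen` (proportion
#' of profile sites not matched identically) and the gap weight
#' `w_g = gap_chars / alen` (proportion of gap characters in the alignment).
#' For any stats with `gap_chars = alen - aqlen` and `aqlen <= plen`,
#' `(1 - p_ARP) * (1 - w_g)` equals the product score exactly.
#'
#' @param stats A `phyrn_alignment_stats`.
#' @return List with elements `p_arp` and `w_g`.
#' @export
arp_gapweight_decomposition <- function(stats) {
  stopifnot(inherits(stats, "phyrn_alignment_stats"))
  if (stats$plen <= 0 || stats$alen <= 0) {
    stop("plen and alen must be positive", call. = FALSE)
  }
  list(p_arp = (stats$plen - stats$ids) / stats$plen,
       w_g = stats$gap_chars / stats$alen)
}

#' Populate the N x M product-score matrix
#'
#' Scores every query against every PSSM in the library. Entry `(n, m)` is
#' the product score of the best local alignment of query `n` versus PSSM
#' `m`, or 0 when no positive-scoring alignment exists. The nominal e-value
#' threshold of 1e10 is implemented literally: every positive local
#' alignment is kept, no significance filter is applied.
#'
#' @param queries Named character vector of protein sequences.
#' @param library A `phyrn_pssm_library` from [build_library()].
#' @param gap_open,gap_extend Affine gap penalties (defaults 11 / 1).
#' @return An object of class `phyrn_matrix`: list with `values`
#'   (N x M numeric in `[0, 1]`), `row_ids`, `col_ids`, `params`.
#' @export
populate_matrix <- function(queries, library, gap_open = 11, gap_extend = 1) {
  stopifnot(inherits(library, "phyrn_pssm_library"))
  queries <- validate_seqs(queries)
  n <- length(queries); m <- length(library$pssms)
  if (n == 0L || m == 0L) stop("queries and library must be nonempty",
                               call. = FALSE)
  enc <- lapply(queries, aa_encode)
  vals <- matrix(0, n, m)
  for (j in seq_len(m)) {
    pssm <- library$pssms[[j]]
    for (i in seq_len(n)) {
      r <- cpp_profile_align(enc[[i]], pssm$scores, pssm$seed,
                             gap_open, gap_extend, TRUE)
      if (isTRUE(r$hit)) {
        st <- alignment_stats(r$ids, r$alen, r$aqlen, pssm$plen, r$score)
        vals[i, j] <- product_score(st)
      }
    }
  }
  structure(list(values = vals,
                 row_ids = names(queries),
                 col_ids = vapply(library$pssms, `[[`, character(1),
                                  "source_id"),
                 params = list(gap_open = gap_open, gap_extend = gap_extend,
                               score_scale = "fraction")),
            class = "phyrn_matrix")
}

# shared id/sequence validation for sets of sequences
validate_seqs <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("sequences must be named", call. = FALSE)
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  }
  if (any(nchar(seqs) == 0L)) stop("empty sequence records", call. = FALSE)
  seqs
}
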