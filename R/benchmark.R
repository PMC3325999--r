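#' Infer a PHYRN tree from sequences
#'
#' The full profile-distance pipeline on a set of sequences: build the
#' per-query PSSM library (gathering against the query set itself by
#' default), populate the product-score matrix, take Euclidean distances,
#' and run neighbor joining.
#'
#' @param queries Named character vector of protein sequences.
#' @param db Gathering database (defaults to the queries).
#' @param max_iter,evalue_cut,gap_open,gap_extend,pseudocount_weight
#'   Profile-building and scoring parameters (see [build_library()] and
#'   [populate_matrix()]).
#' @return List with `tree` (`phylo`), `matrix` (`phyrn_matrix`),
#'   `distances` (square matrix), `library` (`phyrn_pssm_library`).
#' @export
phyrn_infer <- function(queries, db = queries, max_iter = 6L,
                        evalue_cut = 1e-6, gap_open = 11, gap_extend = 1,
                        pseudocount_weight = 10) {
  lib <- build_library(queries, db, max_iter = max_iter,
                       evalue_cut = evalue_cut, gap_open = gap_open,
                       gap_extend = gap_extend,
                       pseudocount_weight = pseudocount_weight)
  pm <- populate_matrix(queries, lib, gap_open = gap_open,
                        gap_extend = gap_extend)
  dm <- euclidean_distances(pm)
  list(tree = nj_tree(dm), matrix = pm, distances = dm, library = lib)
}

# p-distance matrix from the true alignment (pairwise deletion of gap
# columns); pairs sharing no residue-residue column get the saturation
# distance 1
true_alignment_pdistance <- function(family) {
  M <- alignment_int_matrix(family$alignment)
  pid <- cpp_pairwise_identity(M)
  D <- 1 - pid
  D[is.na(D)] <- 1
  diag(D) <- 0
  dimnames(D) <- list(names(family$alignment), names(family$alignment))
  D
}

# p-distance matrix from all-against-all global pairwise alignments
# (BLOSUM62, affine gaps); the classical guide-tree distance
pairwise_alignment_pdistance <- function(seqs, gap_open = 11,
                                         gap_extend = 1) {
  n <- length(seqs)
  ids <- names(seqs)
  aas <- Biostrings::AAStringSet(seqs)
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  sub_mat <- data_env$BLOSUM62
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (j in 2:n) {
    pats <- aas[seq_len(j - 1L)]
    aln <- Biostrings::pairwiseAlignment(
      pats, aas[[j]], substitutionMatrix = sub_mat,
      gapOpening = gap_open, gapExtension = gap_extend, type = "global")
    p <- Biostrings::pid(aln, type = "PID1") / 100
    D[seq_len(j - 1L), j] <- 1 - p
    D[j, seq_len(j - 1L)] <- 1 - p
  }
  D
}

#' Benchmark tree-inference methods on simulated families
#'
#' For every divergence level and replicate, simulates a family of known
#' history, infers a tree with each requested method, and records the
#' Robinson-Foulds distance to the true tree. Methods:
#' \describe{
#'   \item{`phyrn_nj`}{profile product-score distances + NJ
#'     ([phyrn_infer()]).}
#'   \item{`true_alignment_pdistance_nj`}{p-distance on the simulator's true
#'     alignment + NJ (the "perfect alignment" reference).}
#'   \item{`pairwise_pdistance_nj`}{p-distance on all-against-all global
#'     pairwise alignments + NJ (the classical guide-tree baseline).}
#' }
#'
#' @param divergence_levels Numeric vector of mean pairwise PAM targets.
#' @param replicates Replicates per level.
#' @param methods Subset of the method names above.
#' @param n_taxa,mean_seq_len,isr,topology Simulation settings (see
#'   [sim_config()]).
#' @param seed Master seed; every replicate derives its own stream.
#' @return Object of class `phyrn_benchmark`: list with `results` (long
#'   data frame: level, replicate, method, rf, max_rf) and `summary`
#'   (mean RF, SD and replicate count per level and method).
#' @export
benchmark_run <- function(divergence_levels, replicates = 5L,
                          methods = c("phyrn_nj",
                                      "true_alignment_pdistance_nj",
                                      "pairwise_pdistance_nj"),
                          n_taxa = 100L, mean_seq_len = 450L, isr = 0.03,
                          topology = "yule", seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (!length(divergence_levels) || !length(methods) || replicates < 1L) {
    stop("benchmark grid is empty", call. = FALSE)
  }
  rows <- list()
  for (li in seq_along(divergence_levels)) {
    level <- divergence_levels[li]
    for (rep in seq_len(replicates)) {
      cfg <- sim_config(n_taxa = n_taxa, mean_seq_len = mean_seq_len,
                        mean_pairwise_pam = level,
                        indel_to_substitution_ratio = isr,
                        topology_mode = topology,
                        seed = derive_seed(seed, li * 1000L + rep))
      fam <- simulate_family(cfg)
      for (method in methods) {
        est <- switch(method,
          phyrn_nj = phyrn_infer(fam$sequences)$tree,
          true_alignment_pdistance_nj =
            nj_tree(true_alignment_pdistance(fam)),
          pairwise_pdistance_nj =
            nj_tree(pairwise_alignment_pdistance(fam$sequences)))
        rows[[length(rows) + 1L]] <- data.frame(
          level = level, replicate = rep, method = method,
          rf = rf_distance(fam$tree, est),
          max_rf = max_rf(n_taxa), stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  agg <- aggregate(rf ~ level + method, results,
                   function(x) c(mean = mean(x), sd = sd(x), n = length(x)))
  summary <- data.frame(level = agg$level, method = agg$method,
                        mean_rf = agg$rf[, "mean"],
                        sd_rf = ifelse(is.na(agg$rf[, "sd"]), 0,
                                       agg$rf[, "sd"]),
                        n = agg$rf[, "n"], stringsAsFactors = FALSE)
  structure(list(results = results, summary = summary),
            class = "phyrn_benchmark")
}

#' @export
print.phyrn_benchmark <- function(x, ...) {
  cat("PHYRN benchmark (mean RF +/- SD):\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  PAM %-5g %-28s %6.2f (+/-%.2f)  n=%d\n", s$level[i],
                s$method[i], s$mean_rf[i], s$sd_rf[i], s$n[i]))
  }
  invisible(x)
}
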