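# --- bipartition machinery -------------------------------------------------
# A split is canonicalized as the sorted, comma-joined labels of the side
# NOT containing the lexicographically smallest leaf, so the same unrooted
# bipartition always maps to the same string whatever the rooting.

# one canonical split string per internal node (NA for trivial splits:
# singleton side, whole leaf set, or empty complement)
node_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  labels <- tree$tip.label
  ref <- sort(labels)[1]
  pp <- ape::prop.part(tree)
  vapply(seq_along(pp), function(i) {
    clade <- labels[pp[[i]]]
    other <- setdiff(labels, clade)
    if (length(clade) < 2L || length(other) < 2L) return(NA_character_)
    side <- if (ref %in% clade) other else clade
    paste(sort(side), collapse = ",")
  }, character(1))
}

#' Nontrivial bipartitions of a tree
#'
#' The set of unrooted splits induced by the tree's internal edges,
#' excluding trivial splits (those with a singleton side). Each split is a
#' canonical string, so sets from different trees on the same leaves are
#' directly comparable.
#'
#' @param tree A `phylo` object.
#' @return Character vector of canonical split strings (unique).
#' @export
tree_bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  b <- node_bipartitions(tree)
  unique(b[!is.na(b)])
}

check_same_leaves <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees have different leaf label sets", call. = FALSE)
  }
}

#' Robinson-Foulds symmetric distance
#'
#' The cardinality of the symmetric difference of the two trees' nontrivial
#' bipartition sets. Zero iff the unrooted topologies agree; at most
#' `2 (n - 3)` for fully resolved trees on `n` leaves.
#'
#' @param t1,t2 `phylo` trees on identical leaf label sets.
#' @return Non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  check_same_leaves(t1, t2)
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  sum(!(b1 %in% b2)) + sum(!(b2 %in% b1))
}

#' Maximum Robinson-Foulds distance
#'
#' For two fully resolved unrooted trees on `n >= 4` leaves the RF distance
#' is at most `2 (n - 3)` (each tree has `n - 3` nontrivial splits).
#'
#' @param n_leaves Number of leaves (>= 4).
#' @return `2 * (n_leaves - 3)`.
#' @export
max_rf <- function(n_leaves) {
  if (!is.numeric(n_leaves) || length(n_leaves) != 1L || n_leaves < 4 ||
      n_leaves != round(n_leaves)) {
    stop("n_leaves must be a single integer >= 4", call. = FALSE)
  }
  2L * (as.integer(n_leaves) - 3L)
}

#' Consensus-style branch marks against an estimated tree
#'
#' Marks each nontrivial internal branch of the true tree 100 when its
#' bipartition occurs in the estimated tree and 50 otherwise (the two-tree
#' majority-consensus convention: 100 = both trees contain the branch, 50 =
#' only the true tree does). For fully resolved trees the number of 50-marks
#' is `rf_distance / 2`.
#'
#' @param true_tree,est_tree `phylo` trees on the same leaves.
#' @return The true tree with marks as `node.label`, plus attribute
#'   `"marks"`: data frame with columns `split` and `mark`.
#' @export
consensus_marks <- function(true_tree, est_tree) {
  stopifnot(inherits(true_tree, "phylo"), inherits(est_tree, "phylo"))
  check_same_leaves(true_tree, est_tree)
  splits <- tree_bipartitions(true_tree)
  est <- tree_bipartitions(est_tree)
  marks <- ifelse(splits %in% est, 100, 50)
  out <- annotate_splits(true_tree, splits, marks)
  attr(out, "marks") <- data.frame(split = splits, mark = marks,
                                   stringsAsFactors = FALSE)
  out
}

# minimum edge-distance from each node to a descendant leaf
min_leaf_depths <- function(tree) {
  ntip <- length(tree$tip.label)
  h <- rep(Inf, ntip + tree$Nnode)
  h[seq_len(ntip)] <- 0
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1]; ch <- po$edge[k, 2]
    h[par] <- min(h[par], h[ch] + 1)
  }
  h
}

#' Deep-node recapitulation rate
#'
#' Deep nodes are internal nodes of the rooted true tree whose minimum
#' edge-distance to any descendant leaf is at least 2 (ancestors of the last
#' two tiers of leaves). A deep node is recapitulated when the bipartition
#' its subtree induces occurs in the estimated tree; nodes inducing trivial
#' splits (the root, or a complement smaller than two leaves) are contained
#' in every tree and count as recapitulated. The cutoff is exposed via
#' `min_depth` because "last two tiers" admits neighboring readings.
#'
#' @param true_tree Rooted `phylo` true tree.
#' @param est_tree Estimated `phylo` tree on the same leaves.
#' @param min_depth Minimum edge-distance to a descendant leaf for a node to
#'   count as deep (default 2).
#' @return Percentage in `[0, 100]` of deep nodes recapitulated.
#' @export
deep_node_recap <- function(true_tree, est_tree, min_depth = 2L) {
  stopifnot(inherits(true_tree, "phylo"), inherits(est_tree, "phylo"))
  check_same_leaves(true_tree, est_tree)
  ntip <- length(true_tree$tip.label)
  depths <- min_leaf_depths(true_tree)
  deep <- which(depths[(ntip + 1L):(ntip + true_tree$Nnode)] >= min_depth)
  if (!length(deep)) {
    stop("tree has no deep nodes at min_depth = ", min_depth, call. = FALSE)
  }
  node_splits <- node_bipartitions(true_tree)[deep]
  est <- tree_bipartitions(est_tree)
  ok <- is.na(node_splits) | node_splits %in% est
  100 * mean(ok)
}
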