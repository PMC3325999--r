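#' Generate an ultrametric tree for simulated evolution
#'
#' Produces a rooted, binary, strictly clock-like (ultrametric) tree with
#' `n_taxa` uniquely labelled leaves and unit root-to-leaf depth. Branch
#' lengths are later rescaled to a target divergence with [scale_tree()].
#'
#' Topology modes:
#' \describe{
#'   \item{`yule`}{random coalescent-order joins (an unbiased topology).}
#'   \item{`balanced`}{a (near-)perfect binary tree.}
#'   \item{`pectinate`}{a caterpillar (maximally unbalanced, "biased") tree
#'     with join heights equally spaced between 0 and 1.}
#' }
#'
#' @param n_taxa Number of leaves, at least 4.
#' @param topology One of `"yule"`, `"balanced"`, `"pectinate"`.
#' @param seed Integer seed; the same seed always yields the same tree.
#' @return An [ape::read.tree()]-style `phylo` object, rooted, with leaf
#'   labels `t1 ... t<n>` and unit depth.
#' @examples
#' tr <- generate_tree(8, "balanced", seed = 1)
#' @export
generate_tree <- function(n_taxa, topology = c("yule", "balanced", "pectinate"),
                          seed = 1L) {
  topology <- match.arg(topology)
  if (!is.numeric(n_taxa) || length(n_taxa) != 1L || n_taxa < 4 ||
      n_taxa != round(n_taxa)) {
    stop("n_taxa must be a single integer >= 4", call. = FALSE)
  }
  n_taxa <- as.integer(n_taxa)
  labels <- paste0("t", seq_len(n_taxa))
  tr <- switch(topology,
    yule = withr::with_seed(seed, random_join_tree(labels)),
    balanced = balanced_tree(labels),
    pectinate = pectinate_tree(labels)
  )
  tr
}

# random coalescent-order joins under a strict clock: at step k two of the
# surviving lineages, chosen uniformly, are joined at height k / (n - 1), so
# join heights are evenly spaced and the root sits at depth 1. The topology
# distribution is the usual random-joins (coalescent/Yule) one; the even
# spacing keeps pairwise distances concentrated around their mean, which is
# what makes the percent-identity-versus-PAM calibration track the classical
# Dayhoff curve.
random_join_tree <- function(labels) {
  n <- length(labels)
  frags <- labels
  hts <- rep(0, n)
  for (k in seq_len(n - 1)) {
    i <- sample(length(frags), 2L)
    hk <- k / (n - 1)
    nf <- sprintf("(%s:%.15g,%s:%.15g)", frags[i[1]], hk - hts[i[1]],
                  frags[i[2]], hk - hts[i[2]])
    frags <- c(frags[-i], nf)
    hts <- c(hts[-i], hk)
  }
  ape::read.tree(text = paste0(frags, ";"))
}

# rescale an ultrametric tree to unit root-to-leaf depth
rescale_depth <- function(tr) {
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr
}

# near-perfect binary topology by recursive halving, made ultrametric by
# node heights h(leaf) = 0, h(internal) = max(child) + 1, then depth-normalized
balanced_tree <- function(labels) {
  split_nwk <- function(lab) {
    n <- length(lab)
    if (n == 1L) return(lab)
    k <- ceiling(n / 2)
    paste0("(", split_nwk(lab[seq_len(k)]), ",",
           split_nwk(lab[(k + 1):n]), ")")
  }
  tr <- ape::read.tree(text = paste0(split_nwk(labels), ";"))
  ultrametrize_by_levels(tr)
}

pectinate_tree <- function(labels) {
  n <- length(labels)
  nwk <- labels[1]
  for (i in 2:n) nwk <- paste0("(", nwk, ",", labels[i], ")")
  tr <- ape::read.tree(text = paste0(nwk, ";"))
  ultrametrize_by_levels(tr)
}

# assign integer node heights (leaves 0, internal = max child height + 1),
# set edge lengths to height differences, normalize root height to 1
ultrametrize_by_levels <- function(tr) {
  n <- length(tr$tip.label)
  nn <- tr$Nnode
  h <- numeric(n + nn)
  # postorder: children before parents
  po <- ape::reorder.phylo(tr, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1]; ch <- po$edge[k, 2]
    h[par] <- max(h[par], h[ch] + 1)
  }
  root <- n + 1L
  h <- h / h[root]
  tr$edge.length <- h[tr$edge[, 1]] - h[tr$edge[, 2]]
  tr
}

#' Mean pairwise leaf-to-leaf path length of a tree
#'
#' @param tree A `phylo` object with branch lengths.
#' @return Mean, over all unordered leaf pairs, of the patristic distance.
#' @export
mean_pairwise_distance <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  mean(d[lower.tri(d)])
}

#' Rescale a tree to a target mean pairwise divergence
#'
#' Multiplies every branch length by a single factor so that the mean over
#' all unordered leaf pairs of patristic path length equals
#' `mean_pairwise_pam` (in PAM units). Topology is untouched.
#'
#' @param tree A `phylo` object with at least one positive branch length.
#' @param mean_pairwise_pam Positive target mean pairwise distance (PAM).
#' @return The rescaled `phylo` object.
#' @export
scale_tree <- function(tree, mean_pairwise_pam) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.numeric(mean_pairwise_pam) || length(mean_pairwise_pam) != 1L ||
      !is.finite(mean_pairwise_pam) || mean_pairwise_pam <= 0) {
    stop("mean_pairwise_pam must be a single positive number", call. = FALSE)
  }
  cur <- mean_pairwise_distance(tree)
  if (!is.finite(cur) || cur <= 0) {
    stop("cannot scale a tree whose branch lengths are all zero",
         call. = FALSE)
  }
  tree$edge.length <- tree$edge.length * (mean_pairwise_pam / cur)
  tree
}
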