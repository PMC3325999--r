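#' Euclidean distances between profile-score vectors
#'
#' Each query is the vector of its M product scores; the distance between
#' queries X and Y is `sqrt(sum_m (x_m - y_m)^2)`. Being a Euclidean
#' construction the result is symmetric, zero-diagonal, and satisfies the
#' triangle inequality.
#'
#' @param pm A `phyrn_matrix` (or a plain numeric matrix whose rows are the
#'   score vectors, with rownames).
#' @return Square symmetric numeric matrix with query ids as dimnames.
#' @export
euclidean_distances <- function(pm) {
  if (inherits(pm, "phyrn_matrix")) {
    vals <- pm$values
    rownames(vals) <- pm$row_ids
  } else if (is.matrix(pm) && is.numeric(pm)) {
    vals <- pm
  } else {
    stop("pm must be a phyrn_matrix or a numeric matrix", call. = FALSE)
  }
  if (nrow(vals) < 2L) stop("need at least 2 queries", call. = FALSE)
  D <- as.matrix(dist(vals, method = "euclidean"))
  D <- (D + t(D)) / 2   # enforce exact symmetry
  diag(D) <- 0
  D
}

#' Distance tree from a distance matrix
#'
#' Default backend is canonical neighbor joining (Q-criterion joins with
#' Studier-Keppler updates, as implemented in ape), with negative
#' branch-length estimates clamped to zero. Alternative backends sit behind
#' the same interface: `"bionj"` (variance-weighted NJ) and `"fastme"`
#' (balanced minimum evolution, `ape::fastme.bal`); in practice the
#' topology of profile-distance trees is insensitive to this choice. All
#' backends are deterministic for a fixed input matrix.
#'
#' @param dm Square symmetric distance matrix with dimnames (or a `dist`).
#' @param method `"nj"` (default), `"bionj"`, or `"fastme"`.
#' @return An unrooted binary `phylo` tree on the matrix labels.
#' @export
nj_tree <- function(dm, method = c("nj", "bionj", "fastme")) {
  method <- match.arg(method)
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  stopifnot(is.matrix(dm), is.numeric(dm))
  if (nrow(dm) < 3L) stop("neighbor joining needs at least 3 taxa",
                          call. = FALSE)
  tr <- switch(method,
               nj = ape::nj(as.dist(dm)),
               bionj = ape::bionj(as.dist(dm)),
               fastme = ape::fastme.bal(as.dist(dm)))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# splits of the point-estimate tree found in a replicate tree, as a logical
# vector over the point tree's nontrivial splits
splits_present <- function(point_splits, rep_tree) {
  rs <- tree_bipartitions(rep_tree)
  point_splits %in% rs
}

#' Branch support by resampling profile columns
#'
#' The resampling unit is the PSSM column of the N x M product-score matrix
#' (the only exchangeable unit in a profile-distance method; there is no
#' site matrix to resample). `bootstrap` draws M columns with replacement;
#' `jackknife80` draws `floor(0.8 M)` columns without replacement. Each
#' replicate matrix is carried through Euclidean distances and neighbor
#' joining, and the support of an internal branch of the point-estimate
#' tree is the percentage of replicate trees containing its bipartition.
#'
#' @param pm A `phyrn_matrix`.
#' @param mode `"bootstrap"` or `"jackknife80"`.
#' @param replicates Number of resampling replicates (>= 1).
#' @param seed Integer seed; fixed seed reproduces supports exactly.
#' @return The point-estimate `phylo` tree with `node.label` holding the
#'   support percentage of each internal node's branch (root label empty),
#'   plus attribute `"support"` (numeric vector in `[0, 100]`).
#' @export
resample_support <- function(pm, mode = c("bootstrap", "jackknife80"),
                             replicates = 100L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(pm, "phyrn_matrix"))
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  m <- length(pm$col_ids)
  if (m < 2L) stop("need at least 2 profile columns to resample",
                   call. = FALSE)
  vals <- pm$values
  rownames(vals) <- pm$row_ids
  point <- nj_tree(euclidean_distances(vals))
  psplits <- tree_bipartitions(point)
  hits <- numeric(length(psplits))
  withr::with_seed(seed, {
    for (r in seq_len(replicates)) {
      cols <- if (mode == "bootstrap") {
        sample.int(m, m, replace = TRUE)
      } else {
        sample.int(m, floor(0.8 * m))
      }
      rep_tr <- nj_tree(euclidean_distances(vals[, cols, drop = FALSE]))
      hits <- hits + (psplits %in% tree_bipartitions(rep_tr))
    }
  })
  support <- 100 * hits / replicates
  point <- annotate_splits(point, psplits, support)
  attr(point, "support") <- support
  point
}

# write support values onto the node labels of the internal nodes whose
# (nontrivial) splits are listed in `splits`
annotate_splits <- function(tree, splits, values) {
  ntip <- length(tree$tip.label)
  labs <- rep("", tree$Nnode)
  node_splits <- node_bipartitions(tree)
  idx <- match(node_splits, splits)
  has <- !is.na(idx)
  labs[has] <- format(values[idx[has]], trim = TRUE)
  tree$node.label <- labs
  tree
}
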