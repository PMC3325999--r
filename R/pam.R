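# Dayhoff (1978) amino-acid replacement model: symmetric exchangeabilities
# (lower triangle, PAM ordering A R N D C Q E G H I L K M F P S T W Y V) and
# equilibrium frequencies, as distributed with standard phylogenetic software.
DAYHOFF_EXCH <- c(
  27, 98, 120, 36, 89, 198, 240, 23, 65, 41, 26, 72, 18, 250, 409, 371, 0, 24,
  208, 32, 0, 23, 246, 1, 9, 240, 64, 15, 464, 90, 14, 103, 154, 26, 201, 8,
  24, 905, 0, 103, 148, 139, 535, 77, 34, 318, 1, 14, 42, 495, 229, 23, 95,
  15, 0, 134, 1153, 125, 86, 24, 0, 71, 0, 0, 13, 95, 66, 0, 0, 18, 0, 0, 11,
  28, 44, 0, 0, 0, 0, 19, 161, 16, 0, 96, 49, 716, 28, 606, 18, 73, 153, 114,
  0, 153, 56, 53, 0, 0, 35, 81, 43, 61, 11, 83, 30, 0, 51, 79, 34, 0, 22, 37,
  10, 0, 7, 27, 17, 15, 34, 234, 30, 0, 0, 54, 7, 44, 26, 0, 48, 94, 35, 22,
  27, 127, 44, 257, 46, 336, 196, 12, 24, 192, 0, 37, 889, 18, 527, 157, 32,
  17, 33, 46, 28, 175, 243, 0, 33, 96, 136, 0, 13, 10, 92, 17, 62, 104, 0, 0,
  258, 11, 46, 13, 76, 698, 12, 245, 78, 0, 0, 48, 550, 75, 34, 30, 0, 42,
  157, 61, 0, 28)

DAYHOFF_FREQ <- c(
  0.08712691287, 0.04090395910, 0.04043195957, 0.04687195313, 0.03347396653,
  0.03825496175, 0.04952995047, 0.08861191139, 0.03361796638, 0.03688596311,
  0.08535691464, 0.08048191952, 0.01475298525, 0.03977196023, 0.05067994932,
  0.06957693042, 0.05854194146, 0.01049398951, 0.02991597008, 0.06471793528)

#' Dayhoff equilibrium amino-acid frequencies
#'
#' Background frequencies of the 20 amino acids under the Dayhoff model, in
#' the classical PAM alphabet ordering (`A R N D C Q E G H I L K M F P S T W
#' Y V`). These are the default residue background for PSSM construction and
#' the root-sequence distribution of the simulator.
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @export
dayhoff_frequencies <- function() {
  setNames(DAYHOFF_FREQ / sum(DAYHOFF_FREQ), AA_ALPHABET)
}

# Instantaneous Dayhoff rate matrix Q, scaled so the expected number of
# substitutions per site per unit time is 1; 1 PAM = 0.01 units.
dayhoff_rate_matrix <- function() {
  bf <- dayhoff_frequencies()
  A <- matrix(0, 20, 20)
  A[lower.tri(A)] <- DAYHOFF_EXCH
  A <- A + t(A)
  Q <- A %*% diag(bf)
  diag(Q) <- -rowSums(Q)
  Q <- Q / (-sum(bf * diag(Q)))
  dimnames(Q) <- list(AA_ALPHABET, AA_ALPHABET)
  Q
}

# Eigendecomposition of Q via the reversible-chain symmetrization
# S = D^{1/2} Q D^{-1/2}; cached so PAM powers are one diagonal scaling each.
dayhoff_eigen <- function() {
  if (!is.null(.phyrn_cache$eig)) return(.phyrn_cache$eig)
  bf <- dayhoff_frequencies()
  Q <- dayhoff_rate_matrix()
  d <- sqrt(bf)
  S <- diag(d) %*% Q %*% diag(1 / d)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  .phyrn_cache$eig <- list(values = es$values,
                           left = diag(1 / d) %*% es$vectors,
                           right = t(es$vectors) %*% diag(d))
  .phyrn_cache$eig
}

#' Dayhoff PAM transition probability matrix
#'
#' Returns the 20 x 20 matrix of substitution probabilities after `d` PAM
#' units of evolution (the PAM-1 matrix raised to the `round(d)`-th power;
#' 1 PAM = 0.01 expected accepted substitutions per site). Entry `[a, b]` is
#' the probability that a site currently holding residue `a` holds residue
#' `b` after distance `d`. Powers are cached, so repeated calls at the same
#' (rounded) distance are cheap.
#'
#' @param d Non-negative evolutionary distance in PAM units; rounded to the
#'   nearest integer.
#' @return A 20 x 20 row-stochastic matrix with the PAM alphabet as dimnames.
#' @examples
#' P <- pam_matrix(250)
#' sum(dayhoff_frequencies() * diag(P))  # expected identity near 0.20
#' @export
pam_matrix <- function(d) {
  stopifnot(is.numeric(d), length(d) == 1L, is.finite(d), d >= 0)
  d <- round(d)
  key <- paste0("pam", d)
  hit <- .phyrn_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (d == 0) {
    P <- diag(20)
    dimnames(P) <- list(AA_ALPHABET, AA_ALPHABET)
    .phyrn_cache[[key]] <- P
    return(P)
  }
  eig <- dayhoff_eigen()
  P <- eig$left %*% diag(exp(0.01 * d * eig$values)) %*% eig$right
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(AA_ALPHABET, AA_ALPHABET)
  .phyrn_cache[[key]] <- P
  P
}

#' Expected pairwise identity at a given PAM distance
#'
#' The probability that a site is identical in two sequences separated by
#' total path length `d` PAM, under the Dayhoff model at equilibrium:
#' `sum_a f_a P^d[a, a]`. Useful for calibrating simulated divergence levels
#' against percent-identity scales.
#'
#' @param d Evolutionary distance in PAM units (may be a vector).
#' @return Numeric vector of expected identities in `[0, 1]`.
#' @export
pam_expected_identity <- function(d) {
  bf <- dayhoff_frequencies()
  vapply(d, function(di) sum(bf * diag(pam_matrix(di))), numeric(1))
}
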