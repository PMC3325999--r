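#' Read a protein FASTA file
#'
#' Reads amino-acid FASTA via Biostrings, then validates the record set:
#' record ids (the first whitespace-delimited token of each header) must be
#' unique and nonempty, sequences must be nonempty and drawn from the
#' 20-letter alphabet. Lowercase residues are uppercased with a warning.
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase protein sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  seqs <- as.character(x)
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path,
                              call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate FASTA id(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(nchar(seqs) == 0L)) {
    stop("empty FASTA record(s) in ", path, ": ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "), call. = FALSE)
  }
  if (any(grepl("[a-z]", seqs))) {
    warning("lowercase residues uppercased in ", path)
    seqs <- toupper(seqs)
  }
  bad <- !grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"), seqs)
  if (any(bad)) {
    stop("illegal residues in record(s): ", paste(ids[bad], collapse = ", "),
         call. = FALSE)
  }
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of protein sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- validate_seqs(seqs)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), filepath = path,
                              width = 70L)
  invisible(path)
}

#' Read a single newick tree
#'
#' @param path Newick file path containing one tree.
#' @return A `phylo` object.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) stop("cannot parse newick file: ", path, call. = FALSE)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single tree in ", path,
                               call. = FALSE)
    tr <- tr[[1]]
  }
  tr
}

#' Write a tree to newick
#'
#' Branch lengths are printed with enough digits to round-trip; internal
#' node labels (e.g. support values) are preserved.
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}
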