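# Plain-text PSSM library format. One header block, then one record per
# profile: an index line, the seed sequence, the background vector, and one
# line per position carrying 20 scores and 20 frequencies. All reals are
# printed with %.17g so that write -> read -> write is byte-identical.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a PSSM library to a text file
#'
#' @param library A `phyrn_pssm_library`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_pssm_library()]; the round trip is bit-exact.
#' @export
write_pssm_library <- function(library, path) {
  stopifnot(inherits(library, "phyrn_pssm_library"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#PHYRN-PSSM-LIBRARY\tv1", con)
  writeLines(paste0("#METADATA\t",
                    jsonlite::toJSON(library$metadata, auto_unbox = TRUE,
                                     digits = NA)), con)
  writeLines(paste0("#N_PSSMS\t", length(library$pssms)), con)
  for (p in library$pssms) {
    writeLines(paste(">PSSM", p$source_id, p$plen,
                     jsonlite::toJSON(p$params, auto_unbox = TRUE,
                                      digits = NA), sep = "\t"), con)
    writeLines(paste0("SEED\t", aa_decode(p$seed)), con)
    writeLines(paste(c("BG", fmt_num(p$background)), collapse = "\t"), con)
    for (i in seq_len(p$plen)) {
      writeLines(paste(c("P", i, fmt_num(p$scores[i, ]),
                         fmt_num(p$freqs[i, ])), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a PSSM library written by [write_pssm_library()]
#'
#' @param path File path.
#' @return A `phyrn_pssm_library`.
#' @export
read_pssm_library <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#PHYRN-PSSM-LIBRARY")) {
    stop("not a PHYRN PSSM library file: ", path, call. = FALSE)
  }
  meta_line <- sub("^#METADATA\t", "", lines[startsWith(lines, "#METADATA")])
  metadata <- jsonlite::fromJSON(meta_line)
  starts <- which(startsWith(lines, ">PSSM"))
  pssms <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    i <- starts[k]
    hdr <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    source_id <- hdr[2]
    plen <- as.integer(hdr[3])
    params <- jsonlite::fromJSON(hdr[4])
    seed <- aa_encode(sub("^SEED\t", "", lines[i + 1L]))
    bg <- as.numeric(strsplit(lines[i + 2L], "\t",
                              fixed = TRUE)[[1]][-1])
    scores <- matrix(0, plen, 20)
    freqs <- matrix(0, plen, 20)
    for (p in seq_len(plen)) {
      f <- strsplit(lines[i + 2L + p], "\t", fixed = TRUE)[[1]]
      v <- as.numeric(f[-(1:2)])
      scores[p, ] <- v[1:20]
      freqs[p, ] <- v[21:40]
    }
    pssms[[k]] <- structure(
      list(source_id = source_id, seed = seed, plen = plen,
           scores = scores, freqs = freqs,
           background = setNames(bg, AA_ALPHABET), params = params),
      class = "phyrn_pssm")
  }
  structure(list(pssms = pssms, metadata = metadata),
            class = "phyrn_pssm_library")
}

#' Write a product-score matrix as TSV plus a JSON sidecar
#'
#' The TSV carries row and column headers; parameters and provenance go to
#' `<path>.json`. [read_score_matrix()] round-trips exactly.
#'
#' @param pm A `phyrn_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(pm, path) {
  stopifnot(inherits(pm, "phyrn_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("query", pm$col_ids), collapse = "\t"), con)
  for (i in seq_along(pm$row_ids)) {
    writeLines(paste(c(pm$row_ids[i], fmt_num(pm$values[i, ])),
                     collapse = "\t"), con)
  }
  jsonlite::write_json(pm$params, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a product-score matrix written by [write_score_matrix()]
#'
#' @param path TSV path (the `<path>.json` sidecar is read when present).
#' @return A `phyrn_matrix`.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  col_ids <- hdr[-1]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  row_ids <- vapply(body, `[[`, character(1), 1)
  vals <- t(vapply(body, function(f) as.numeric(f[-1]),
                   numeric(length(col_ids))))
  if (length(col_ids) == 1L) vals <- matrix(vals, ncol = 1L)
  side <- paste0(path, ".json")
  params <- if (file.exists(side)) jsonlite::fromJSON(side) else list()
  structure(list(values = unname(vals), row_ids = row_ids,
                 col_ids = col_ids, params = params),
            class = "phyrn_matrix")
}

#' Write a distance matrix
#'
#' `format = "tsv"` writes a square tab-separated matrix with row and column
#' headers; `format = "phylip"` writes the square PHYLIP format (taxon count
#' line, then one name-prefixed row per taxon) for interoperability with
#' classical tree programs.
#'
#' @param dm Square symmetric numeric matrix with dimnames.
#' @param path Output path.
#' @param format `"tsv"` or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  ids <- rownames(dm)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "tsv") {
    writeLines(paste(c("id", ids), collapse = "\t"), con)
    for (i in seq_along(ids)) {
      writeLines(paste(c(ids[i], fmt_num(dm[i, ])), collapse = "\t"), con)
    }
  } else {
    writeLines(sprintf("%5d", nrow(dm)), con)
    for (i in seq_along(ids)) {
      writeLines(paste(c(sprintf("%-10s", ids[i]),
                         sprintf("%.9f", dm[i, ])), collapse = " "), con)
    }
  }
  invisible(path)
}

#' Read a TSV distance matrix written by [write_distance_matrix()]
#'
#' @param path TSV path.
#' @return Square numeric matrix with dimnames.
#' @export
read_distance_matrix <- function(path) {
  lines <- readLines(path)
  ids <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  vals <- t(vapply(body, function(f) as.numeric(f[-1]),
                   numeric(length(ids))))
  dimnames(vals) <- list(vapply(body, `[[`, character(1), 1), ids)
  vals
}
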