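#' Read an aligned FASTA multiple sequence alignment
#'
#' Sequence letters are uppercased and '.' gap characters normalized to '-'.
#' Identifiers are the first whitespace-delimited token of each header and
#' must be unique; all rows must have equal aligned length.
#'
#' @param path FASTA file path.
#' @return an \code{\link[Biostrings]{AAStringSet}} of aligned rows.
#' @export
readMsaFasta <- function(path) {
  if (!file.exists(path)) stop("MSA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) < 2L) stop("an alignment needs at least 2 sequences, got ", length(ss))
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in MSA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(ss))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  w <- nchar(seqs)
  if (length(unique(w)) != 1L) {
    bad <- ids[w != stats::median(w)]
    stop("ragged alignment: sequence(s) ", paste(bad, collapse = ", "),
         " differ in length (widths ", paste(unique(w), collapse = "/"), ")")
  }
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write an alignment to FASTA
#' @param msa an AAStringSet.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeMsaFasta <- function(msa, path) {
  Biostrings::writeXStringSet(msa, path)
  invisible(path)
}

#' Alignment as a character matrix (rows = sequences, columns = positions)
#' @param msa an AAStringSet of equal-width rows.
#' @export
msaMatrix <- function(msa) {
  m <- do.call(rbind, strsplit(as.character(msa), ""))
  rownames(m) <- names(msa)
  m
}
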