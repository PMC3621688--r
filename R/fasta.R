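#' Read a FASTA file into a DNAStringSet
#'
#' Sequences are uppercased on read; the record id (first whitespace-delimited
#' token of the header) becomes the element name and the remainder of the
#' header is kept in `mcols(x)$description`.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by record id.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L)
    stop("no sequences in FASTA file '", path, "'")
  hdr <- names(x)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  if (any(!nzchar(id)))
    stop("FASTA file '", path, "' contains a record with an empty id")
  dup <- unique(id[duplicated(id)])
  if (length(dup))
    stop("duplicate sequence id in '", path, "': ", dup[1L])
  if (any(Biostrings::width(x) == 0L))
    stop("FASTA file '", path, "' contains a zero-length sequence")
  out <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(out) <- id
  S4Vectors::mcols(out)$description <- desc
  out
}

#' Write a DNAStringSet to FASTA
#'
#' @param x A named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
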