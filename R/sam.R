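# SAM text I/O. Records are held in a plain data frame with one row per
# read; POS is converted to a 0-based start at the parse boundary (NA when
# the file stores 0, i.e. unmapped/unplaced) and back on write. Optional
# tags are carried opaquely as a single tab-joined string so that
# write_sam(read_sam(x)) reproduces every field byte-for-byte.

FLAG_PAIRED <- 0x1L
FLAG_PROPER <- 0x2L
FLAG_UNMAPPED <- 0x4L
FLAG_REVERSE <- 0x10L
FLAG_SECONDARY <- 0x100L
FLAG_SUPPLEMENTARY <- 0x800L

empty_sam_records <- function() {
  data.frame(qname = character(), flag = integer(), rname = character(),
             pos = integer(), mapq = integer(), cigar = character(),
             rnext = character(), pnext = integer(), tlen = integer(),
             seq = character(), qual = character(), tags = character(),
             stringsAsFactors = FALSE)
}

#' Construct SAM records
#'
#' Convenience row builder used by the simulators and tests. `pos` is
#' 0-based (NA for unmapped).
#'
#' @param qname,flag,rname,pos,mapq,cigar,rnext,pnext,tlen,seq,qual,tags
#'   Vectors recycled to a common length; `tags` is the raw tab-joined
#'   optional-field string (`""` for none).
#' @return A SAM record data frame.
#' @export
sam_records <- function(qname, flag = 0L, rname = "*", pos = NA_integer_,
                        mapq = 0L, cigar = "*", rnext = "*", pnext = 0L,
                        tlen = 0L, seq = "*", qual = "*", tags = "") {
  data.frame(qname = qname, flag = as.integer(flag), rname = rname,
             pos = as.integer(pos), mapq = as.integer(mapq), cigar = cigar,
             rnext = rnext, pnext = as.integer(pnext),
             tlen = as.integer(tlen), seq = seq, qual = qual, tags = tags,
             stringsAsFactors = FALSE)
}

is_mapped <- function(records) bitwAnd(records$flag, FLAG_UNMAPPED) == 0L

validate_sam_records <- function(records, where = "SAM input") {
  chk <- which(is_mapped(records) & records$cigar != "*" & records$seq != "*")
  for (i in chk) {
    cp <- cigar_parse(records$cigar[i])
    if (cigar_query_len(cp) != nchar(records$seq[i]))
      stop(where, ": CIGAR and sequence length disagree for read '",
           records$qname[i], "' (", records$cigar[i], " vs ",
           nchar(records$seq[i]), " bases)")
  }
  invisible(records)
}

#' Read a SAM file
#'
#' @param path Path to a SAM text file.
#' @return A list with `header` (character vector of `@` lines, verbatim)
#'   and `records` (data frame; `pos` is 0-based, NA when the file stores
#'   POS 0; optional tags tab-joined in `tags`).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  header <- lines[is_hdr]
  body <- lines[!is_hdr & nzchar(lines)]
  if (length(body) == 0L)
    return(list(header = header, records = empty_sam_records()))
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L))
    stop("SAM file '", path, "': record with fewer than 11 fields ('",
         body[nf < 11L][1L], "')")
  col <- function(i) vapply(parts, `[[`, "", i)
  posf <- as.integer(col(4L))
  rec <- data.frame(
    qname = col(1L), flag = as.integer(col(2L)), rname = col(3L),
    pos = ifelse(posf == 0L, NA_integer_, posf - 1L),
    mapq = as.integer(col(5L)), cigar = col(6L), rnext = col(7L),
    pnext = as.integer(col(8L)), tlen = as.integer(col(9L)),
    seq = col(10L), qual = col(11L),
    tags = vapply(parts, function(p)
      if (length(p) > 11L) paste(p[12:length(p)], collapse = "\t") else "", ""),
    stringsAsFactors = FALSE)
  validate_sam_records(rec, where = paste0("SAM file '", path, "'"))
  list(header = header, records = rec)
}

#' Write a SAM file
#'
#' Inverse of [read_sam()]: serializing a just-read file reproduces it
#' byte-for-byte (mandatory fields and tags) for valid input.
#'
#' @param path Output path.
#' @param header Character vector of header lines (written verbatim).
#' @param records SAM record data frame.
#' @export
write_sam <- function(path, header, records) {
  lines <- header
  if (nrow(records) > 0L) {
    posf <- ifelse(is.na(records$pos), 0L, records$pos + 1L)
    fields <- paste(records$qname, records$flag, records$rname, posf,
                    records$mapq, records$cigar, records$rnext,
                    records$pnext, records$tlen, records$seq, records$qual,
                    sep = "\t")
    lines <- c(lines, ifelse(nzchar(records$tags),
                             paste(fields, records$tags, sep = "\t"), fields))
  }
  writeLines(lines, path)
  invisible(path)
}

# Value of an integer tag (e.g. "AS"), NA when absent.
sam_tag_int <- function(tags, tag) {
  m <- regexec(paste0("(^|\t)", tag, ":i:(-?[0-9]+)"), tags)
  vapply(regmatches(tags, m), function(g)
    if (length(g)) as.integer(g[[3L]]) else NA_integer_, 0L)
}

# Drop named tags (default MD/NM) from a raw tag string.
sam_drop_tags <- function(tags, drop = c("MD", "NM")) {
  vapply(tags, function(s) {
    if (!nzchar(s)) return(s)
    p <- strsplit(s, "\t", fixed = TRUE)[[1L]]
    p <- p[!(substr(p, 1L, 2L) %in% drop)]
    paste(p, collapse = "\t")
  }, "", USE.NAMES = FALSE)
}
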