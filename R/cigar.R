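# CIGAR utilities. CIGARs are carried as strings in SAM records and parsed
# on demand into parallel length/op vectors.

.cigar_re <- "^([0-9]+[MIDNSHP=X])+$"

#' Parse a CIGAR string
#'
#' @param cigar A single CIGAR string (e.g. `"10S90M"`). `"*"` is not a
#'   parseable CIGAR and raises an error.
#' @return A list with integer vector `len` and character vector `op`.
#' @keywords internal
cigar_parse <- function(cigar) {
  if (length(cigar) != 1L || is.na(cigar) || cigar == "*" ||
      !grepl(.cigar_re, cigar))
    stop("malformed CIGAR string: '", cigar, "'")
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  list(len = len, op = op)
}

cigar_string <- function(len, op) {
  if (length(len) == 0L) return("*")
  paste0(len, op, collapse = "")
}

# Merge adjacent same-code operations and drop zero-length ones; a canonical
# CIGAR never repeats a code in adjacent slots.
cigar_canonical <- function(len, op) {
  keep <- len > 0L
  len <- len[keep]; op <- op[keep]
  if (length(len) <= 1L) return(list(len = len, op = op))
  grp <- cumsum(c(TRUE, op[-1L] != op[-length(op)]))
  list(len = as.integer(tapply(len, grp, sum)), op = op[!duplicated(grp)])
}

# query-consuming ops: M I S = X; reference-consuming: M D N = X
cigar_query_len <- function(cp) sum(cp$len[cp$op %in% c("M", "I", "S", "=", "X")])
cigar_ref_len <- function(cp) sum(cp$len[cp$op %in% c("M", "D", "N", "=", "X")])
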