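# GFF3 reading/writing. File coordinates are 1-based inclusive; everything
# this package hands around internally is 0-based half-open, and the
# conversion happens here and nowhere else.

gff3_decode <- function(x) vapply(x, utils::URLdecode, "", USE.NAMES = FALSE)

gff3_encode <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  gsub("\t", "%09", x, fixed = TRUE)
}

parse_gff3_attributes <- function(s, line_no) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
  parts <- parts[nzchar(trimws(parts))]
  kv <- regmatches(parts, regexec("^\\s*([^=]+)=(.*)$", parts))
  bad <- lengths(kv) != 3L
  if (any(bad))
    stop("GFF3 line ", line_no, ": malformed attribute '", parts[bad][1L], "'")
  vals <- gff3_decode(vapply(kv, `[[`, "", 3L))
  names(vals) <- gff3_decode(trimws(vapply(kv, `[[`, "", 2L)))
  vals
}

#' Read gene features from a GFF3 file
#'
#' Keeps only rows whose feature type matches `feature_type` (column 3),
#' preserving file order. Each kept feature must carry an `ID` attribute,
#' which becomes `gene_id`. Coordinates in the returned data frame are
#' 0-based half-open.
#'
#' @param path Path to a GFF3 file.
#' @param feature_type Feature type to keep (default `"gene"`; set to
#'   `"mRNA"` for transcript-level annotations).
#' @return A data frame with columns `seqid`, `type`, `start`, `end`
#'   (0-based half-open), `strand`, `gene_id`, and a list column
#'   `attributes` of named character vectors (percent-decoded).
#' @export
read_gff3_genes <- function(path, feature_type = "gene") {
  lines <- readLines(path)
  rows <- list()
  attrs_list <- list()
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(line) || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L)
      stop("GFF3 line ", ln, ": expected 9 tab-separated columns, got ", length(f))
    if (f[3L] != feature_type) next
    start <- suppressWarnings(as.integer(f[4L]))
    end <- suppressWarnings(as.integer(f[5L]))
    if (is.na(start) || is.na(end) || start < 1L || start > end)
      stop("GFF3 line ", ln, ": invalid interval ", f[4L], "-", f[5L])
    attrs <- parse_gff3_attributes(f[9L], ln)
    if (!("ID" %in% names(attrs)))
      stop("GFF3 line ", ln, ": ", feature_type, " feature lacks an ID attribute")
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = f[1L], type = f[3L], start = start - 1L, end = end,
      strand = f[7L], gene_id = attrs[["ID"]], stringsAsFactors = FALSE)
    attrs_list[[length(attrs_list) + 1L]] <- attrs
  }
  if (length(rows) == 0L) {
    out <- data.frame(seqid = character(), type = character(),
                      start = integer(), end = integer(),
                      strand = character(), gene_id = character(),
                      stringsAsFactors = FALSE)
    out$attributes <- list()
    return(out)
  }
  out <- do.call(rbind, rows)
  out$attributes <- attrs_list
  rownames(out) <- NULL
  out
}

#' Write features to GFF3
#'
#' Serializes a feature data frame in the layout produced by
#' [read_gff3_genes()] back to 1-based inclusive GFF3.
#'
#' @param features Feature data frame (internal 0-based half-open coords).
#' @param path Output path.
#' @export
write_gff3 <- function(features, path) {
  lines <- "##gff-version 3"
  if (nrow(features) > 0L) {
    attr_str <- vapply(seq_len(nrow(features)), function(i) {
      a <- features$attributes[[i]]
      if (is.null(a) || length(a) == 0L)
        a <- c(ID = features$gene_id[i])
      paste0(gff3_encode(names(a)), "=", gff3_encode(unname(a)), collapse = ";")
    }, "")
    lines <- c(lines, paste(features$seqid, ".", features$type,
                            features$start + 1L, features$end, ".",
                            features$strand, ".", attr_str, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
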