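# Run configuration: a small INI file with a [readlift] section, plus the
# optional query-gene -> target relation preference table.

.required_keys <- c("reads_sam", "query_genome", "query_gff3",
                    "target_genome", "gene_alignment_sam", "output_sam")
.path_keys <- c(.required_keys, "relation_file", "maps_file", "regions_fasta")

#' Read a run configuration file
#'
#' Parses an INI file with a `[readlift]` section. Required keys are the six
#' input/output paths (`reads_sam`, `query_genome`, `query_gff3`,
#' `target_genome`, `gene_alignment_sam`, `output_sam`). Optional keys with
#' defaults: `flank_upstream` (500), `flank_downstream` (500), `n_jobs` (1),
#' `min_mapped_bases` (1), `feature_type` ("gene"),
#' `reciprocal_filter` (false). Optional paths without defaults:
#' `relation_file`, `maps_file`, `regions_fasta`. Relative paths are resolved
#' against the directory containing the configuration file.
#'
#' @param path Path to the INI file.
#' @return A named list of settings.
#' @export
read_settings <- function(path) {
  if (!file.exists(path))
    stop("settings file '", path, "' does not exist")
  lines <- trimws(readLines(path))
  section <- ""
  kv <- list()
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(line) || startsWith(line, "#") || startsWith(line, ";")) next
    sec <- regmatches(line, regexec("^\\[(.+)\\]$", line))[[1L]]
    if (length(sec)) { section <- sec[[2L]]; next }
    m <- regmatches(line, regexec("^([^=]+)=(.*)$", line))[[1L]]
    if (length(m) != 3L)
      stop("settings file '", path, "' line ", ln, ": expected 'key = value'")
    if (section == "readlift")
      kv[[trimws(m[[2L]])]] <- trimws(m[[3L]])
  }
  for (k in .required_keys)
    if (is.null(kv[[k]]))
      stop("settings file '", path, "' is missing required key '", k, "'")

  get_int <- function(key, default) {
    if (is.null(kv[[key]])) return(default)
    v <- suppressWarnings(as.integer(kv[[key]]))
    if (is.na(v)) stop("settings key '", key, "' must be an integer")
    v
  }
  get_bool <- function(key, default) {
    if (is.null(kv[[key]])) return(default)
    tolower(kv[[key]]) %in% c("1", "true", "yes", "on")
  }
  s <- list(
    reads_sam = kv$reads_sam, query_genome = kv$query_genome,
    query_gff3 = kv$query_gff3, target_genome = kv$target_genome,
    gene_alignment_sam = kv$gene_alignment_sam, output_sam = kv$output_sam,
    relation_file = kv$relation_file, maps_file = kv$maps_file,
    regions_fasta = kv$regions_fasta,
    flank_upstream = get_int("flank_upstream", 500L),
    flank_downstream = get_int("flank_downstream", 500L),
    n_jobs = get_int("n_jobs", 1L),
    min_mapped_bases = get_int("min_mapped_bases", 1L),
    feature_type = if (is.null(kv$feature_type)) "gene" else kv$feature_type,
    reciprocal_filter = get_bool("reciprocal_filter", FALSE))
  if (s$flank_upstream < 0L || s$flank_downstream < 0L)
    stop("flank lengths must be non-negative")
  if (s$n_jobs < 1L) stop("n_jobs must be >= 1")
  if (s$min_mapped_bases < 1L) stop("min_mapped_bases must be >= 1")
  base <- dirname(normalizePath(path, mustWork = FALSE))
  for (k in .path_keys)
    if (!is.null(s[[k]]) && !grepl("^(/|[A-Za-z]:)", s[[k]]))
      s[[k]] <- file.path(base, s[[k]])
  s
}

#' Read a relation preference table
#'
#' Two tab-separated columns: query gene id and a target specification,
#' either a sequence name (`chr2`) or a sequence with a 1-based inclusive
#' interval (`chr2:100-900`). A gene may appear on several lines; all its
#' rows are admissible targets. Returned intervals are 0-based half-open
#' (NA when absent).
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `gene_id`, `target_seq`, `start`, `end`.
#' @export
read_relations <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(trimws(line)) || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L)
      stop("relation file '", path, "' line ", ln,
           ": expected two tab-separated columns")
    spec <- f[[2L]]
    m <- regmatches(spec, regexec("^(.*):([0-9]+)-([0-9]+)$", spec))[[1L]]
    if (length(m) == 4L) {
      start <- as.integer(m[[3L]]); end <- as.integer(m[[4L]])
      if (start > end || start < 1L)
        stop("relation file '", path, "' line ", ln,
             ": malformed interval '", spec, "'")
      out[[length(out) + 1L]] <- data.frame(
        gene_id = f[[1L]], target_seq = m[[2L]],
        start = start - 1L, end = end, stringsAsFactors = FALSE)
    } else {
      out[[length(out) + 1L]] <- data.frame(
        gene_id = f[[1L]], target_seq = spec,
        start = NA_integer_, end = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(gene_id = character(), target_seq = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
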