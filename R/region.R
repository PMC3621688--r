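# Flanked gene regions. The upstream flank extends 5' of the transcription
# start site (left of the gene on "+", right on "-"), the downstream flank
# 3' of the gene end; both are truncated silently at chromosome boundaries.
# Extracted sequences are ALWAYS forward-strand genomic sequence — the
# long-sequence aligner, not this package, detects orientation — so the
# downstream coordinate composition needs only the alignment's strand flag.

#' Compute the flanked region of one gene
#'
#' @param feature A list or one-row data frame with `gene_id`, `seqid`,
#'   `start`, `end` (0-based half-open), `strand`.
#' @param flank_upstream,flank_downstream Flank lengths in bp (>= 0).
#' @param chrom_length Length of the feature's chromosome.
#' @return A list with `gene_id`, `chrom`, `gene_start`, `gene_end`,
#'   `strand`, `region_start`, `region_end` (all coordinates 0-based
#'   half-open).
#' @export
compute_region <- function(feature, flank_upstream, flank_downstream,
                           chrom_length) {
  stopifnot(flank_upstream >= 0L, flank_downstream >= 0L)
  strand <- feature$strand
  if (identical(strand, ".")) {
    warning("feature '", feature$gene_id,
            "' is unstranded; treating as '+'")
    strand <- "+"
  }
  if (!strand %in% c("+", "-"))
    stop("feature '", feature$gene_id, "' has invalid strand '", strand, "'")
  if (feature$start >= chrom_length || feature$end <= 0L)
    stop("feature '", feature$gene_id,
         "' lies entirely outside its chromosome")
  if (feature$start < 0L || feature$end > chrom_length)
    stop("feature '", feature$gene_id, "' extends past chromosome bounds")
  if (strand == "+") {
    rs <- feature$start - flank_upstream
    re <- feature$end + flank_downstream
  } else {
    rs <- feature$start - flank_downstream
    re <- feature$end + flank_upstream
  }
  list(gene_id = feature$gene_id, chrom = feature$seqid,
       gene_start = feature$start, gene_end = feature$end, strand = strand,
       region_start = max(0L, as.integer(rs)),
       region_end = min(as.integer(chrom_length), as.integer(re)))
}

#' Compute flanked regions for a feature table
#'
#' @param features Feature data frame from [read_gff3_genes()].
#' @param flank_upstream,flank_downstream Flank lengths in bp.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @return A data frame with one row per feature: `gene_id`, `chrom`,
#'   `gene_start`, `gene_end`, `strand`, `region_start`, `region_end`.
#' @export
compute_regions <- function(features, flank_upstream, flank_downstream,
                            chrom_lengths) {
  miss <- setdiff(unique(features$seqid), names(chrom_lengths))
  if (length(miss))
    stop("chromosome '", miss[1L], "' has no known length")
  rows <- lapply(seq_len(nrow(features)), function(i) {
    r <- compute_region(features[i, ], flank_upstream, flank_downstream,
                        chrom_lengths[[features$seqid[i]]])
    data.frame(gene_id = r$gene_id, chrom = r$chrom,
               gene_start = r$gene_start, gene_end = r$gene_end,
               strand = r$strand, region_start = r$region_start,
               region_end = r$region_end, stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(gene_id = character(), chrom = character(),
                      gene_start = integer(), gene_end = integer(),
                      strand = character(), region_start = integer(),
                      region_end = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Serialize region provenance headers
#'
#' The FASTA id of an extracted region encodes its provenance as
#' `<gene_id>::<chrom>:<region_start>-<region_end>(<strand>)` with 0-based
#' half-open coordinates; the aligner carries it through as QNAME, which is
#' how the coordinate-map builder recovers where each aligned sequence came
#' from.
#'
#' @param regions Region data frame from [compute_regions()].
#' @return Character vector of header ids.
#' @export
region_header <- function(regions) {
  sprintf("%s::%s:%d-%d(%s)", regions$gene_id, regions$chrom,
          regions$region_start, regions$region_end, regions$strand)
}

#' Parse a region provenance header
#'
#' Inverse of [region_header()]. Gene bounds without flanks are not
#' recoverable from the header and are set equal to the region bounds.
#'
#' @param id A single header id.
#' @return A region list as returned by [compute_region()].
#' @export
parse_region_header <- function(id) {
  m <- regmatches(id,
    regexec("^(.+)::([^:]+):([0-9]+)-([0-9]+)\\(([+-])\\)$", id))[[1L]]
  if (length(m) != 6L)
    stop("malformed region header: '", id, "'")
  rs <- as.integer(m[[4L]]); re <- as.integer(m[[5L]])
  if (rs >= re)
    stop("malformed region header (empty interval): '", id, "'")
  list(gene_id = m[[2L]], chrom = m[[3L]], gene_start = rs, gene_end = re,
       strand = m[[6L]], region_start = rs, region_end = re)
}

#' Extract region sequences from a genome
#'
#' One FASTA record per region, containing the forward-strand genomic
#' substring `[region_start, region_end)` and named by [region_header()].
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param regions Region data frame from [compute_regions()].
#' @return A [Biostrings::DNAStringSet] in input region order.
#' @export
extract_sequences <- function(genome, regions) {
  miss <- setdiff(unique(regions$chrom), names(genome))
  if (length(miss))
    stop("chromosome '", miss[1L], "' not present in the genome FASTA")
  if (nrow(regions) == 0L)
    return(Biostrings::DNAStringSet())
  out <- Biostrings::subseq(genome[regions$chrom],
                            start = regions$region_start + 1L,
                            end = regions$region_end)
  names(out) <- region_header(regions)
  out
}
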