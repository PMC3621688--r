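# Paralog disambiguation: reduce one-to-multi / multi-to-multi gene-to-
# target alignments to at most one alignment per query gene. User-supplied
# relation preferences are applied first, then alignment score; the
# tie-break order (score desc, target sequence asc, target start asc, input
# order) is total, so the result is independent of input permutation.

#' Alignment score of a gene-to-target SAM record
#'
#' The value of the `AS:i` tag when present, otherwise the number of
#' query-aligned bases (sum of M/=/X CIGAR lengths) — a fallback that keeps
#' aligner output without AS tags (e.g. converted BLAT hits) usable.
#'
#' @param record One-row SAM record data frame (mapped).
#' @return A single number.
#' @export
alignment_score <- function(record) {
  v <- sam_tag_int(record$tags, "AS")
  if (!is.na(v)) return(v)
  cp <- cigar_parse(record$cigar)
  sum(cp$len[cp$op %in% c("M", "=", "X")])
}

#' Score and annotate gene-region alignments
#'
#' Discards unmapped, secondary and supplementary records; parses the
#' region provenance header from QNAME; computes the target span and score.
#'
#' @param records SAM record data frame (gene regions vs target genome).
#' @return A data frame with `gene_id`, `target_seq`, `t_start`, `t_end`
#'   (0-based half-open), `score`, `idx` (row index into `records`).
#' @export
scored_alignments <- function(records) {
  drop <- FLAG_UNMAPPED + FLAG_SECONDARY + FLAG_SUPPLEMENTARY
  keep <- which(bitwAnd(records$flag, drop) == 0L & !is.na(records$pos) &
                records$cigar != "*")
  rows <- lapply(keep, function(i) {
    reg <- parse_region_header(records$qname[i])
    cp <- cigar_parse(records$cigar[i])
    data.frame(gene_id = reg$gene_id, target_seq = records$rname[i],
               t_start = records$pos[i],
               t_end = records$pos[i] + cigar_ref_len(cp),
               score = alignment_score(records[i, ]), idx = i,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(gene_id = character(), target_seq = character(),
                      t_start = integer(), t_end = integer(),
                      score = numeric(), idx = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Does an alignment satisfy a relation preference?
#'
#' True iff the alignment's target sequence equals the preference's and,
#' when the preference carries an interval, the target span overlaps it by
#' at least one base.
#'
#' @param aln One row of [scored_alignments()] output.
#' @param pref One row of [read_relations()] output.
#' @return Logical scalar.
#' @export
matches_preference <- function(aln, pref) {
  if (aln$target_seq != pref$target_seq) return(FALSE)
  if (is.na(pref$start)) return(TRUE)
  aln$t_start < pref$end && pref$start < aln$t_end
}

#' Resolve gene-to-target alignments to at most one per gene
#'
#' Per gene: candidates failing every preference for that gene are dropped
#' (genes without preferences keep all candidates); the highest-scoring
#' survivor wins, ties broken by smallest target sequence name, then
#' smallest target start, then input order. With
#' `reciprocal_filter = TRUE`, winning alignments whose target spans
#' mutually overlap by more than 50% of the shorter span are additionally
#' reduced to the single best under the same order, so no target region
#' keeps two genes.
#'
#' @param records SAM record data frame of gene-region alignments.
#' @param preferences Optional data frame from [read_relations()].
#' @param reciprocal_filter Apply the pairwise >50%-overlap filter.
#' @return A list with `alignments` (winning rows of
#'   [scored_alignments()], sorted by `gene_id`) and `records` (the
#'   corresponding SAM records).
#' @export
resolve_alignments <- function(records, preferences = NULL,
                               reciprocal_filter = FALSE) {
  al <- scored_alignments(records)
  if (!is.null(preferences) && nrow(preferences) > 0L) {
    absent <- setdiff(unique(preferences$gene_id), unique(al$gene_id))
    if (length(absent))
      warning("relation preferences for gene(s) with no alignment: ",
              paste(absent, collapse = ", "))
    keep <- vapply(seq_len(nrow(al)), function(i) {
      prefs <- preferences[preferences$gene_id == al$gene_id[i], , drop = FALSE]
      if (nrow(prefs) == 0L) return(TRUE)
      any(vapply(seq_len(nrow(prefs)), function(j)
        matches_preference(al[i, ], prefs[j, ]), TRUE))
    }, TRUE)
    al <- al[keep, , drop = FALSE]
  }
  if (nrow(al) > 0L) {
    # total tie-break order: score desc, target_seq asc, t_start asc, idx asc
    ord <- order(-al$score, al$target_seq, al$t_start, al$idx)
    al <- al[ord, , drop = FALSE]
    al <- al[!duplicated(al$gene_id), , drop = FALSE]
    if (reciprocal_filter && nrow(al) > 1L) {
      kept <- integer(0)
      for (i in seq_len(nrow(al))) {   # already in best-first order
        clash <- FALSE
        for (k in kept) {
          if (al$target_seq[i] != al$target_seq[k]) next
          ov <- min(al$t_end[i], al$t_end[k]) - max(al$t_start[i], al$t_start[k])
          shorter <- min(al$t_end[i] - al$t_start[i],
                         al$t_end[k] - al$t_start[k])
          if (ov > 0.5 * shorter) { clash <- TRUE; break }
        }
        if (!clash) kept <- c(kept, i)
      }
      al <- al[kept, , drop = FALSE]
    }
    al <- al[order(al$gene_id), , drop = FALSE]
    rownames(al) <- NULL
  }
  list(alignments = al, records = records[al$idx, , drop = FALSE])
}
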