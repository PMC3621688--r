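# Read transformation: compose each read's alignment (read <-> query
# genome) with a coordinate map (query genome <-> target genome) into a
# valid target-coordinate SAM record. Reads on non-corresponding positions
# come out flagged unmapped.

revcomp_chr <- function(s) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
}

reverse_chr <- function(s) {
  paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
}

# Per-base layout of a mapped read in stored (SEQ) orientation: for each
# SEQ base its class ("M" aligned, "I" inserted, "S" clipped) and, for M
# bases, the 0-based query-genome position. Hard-clip lengths are kept so
# they can be re-attached to the output CIGAR.
read_base_layout <- function(pos, cigar) {
  cp <- cigar_parse(cigar)
  L <- cigar_query_len(cp)
  cls <- character(L)
  qpos <- rep(NA_integer_, L)
  i <- 0L; q <- pos
  lead_h <- 0L; trail_h <- 0L
  for (k in seq_along(cp$op)) {
    op <- cp$op[k]; n <- cp$len[k]
    if (op %in% c("M", "=", "X")) {
      cls[i + seq_len(n)] <- "M"
      qpos[i + seq_len(n)] <- q + seq_len(n) - 1L
      i <- i + n; q <- q + n
    } else if (op == "I") {
      cls[i + seq_len(n)] <- "I"; i <- i + n
    } else if (op == "S") {
      cls[i + seq_len(n)] <- "S"; i <- i + n
    } else if (op %in% c("D", "N")) {
      q <- q + n
    } else if (op == "H") {
      if (i == 0L) lead_h <- lead_h + n else trail_h <- trail_h + n
    }
  }
  list(cls = cls, qpos = qpos, lead_h = lead_h, trail_h = trail_h)
}

# Composition core, shared by compose_cigar() and the batch transformer.
# Returns NULL when no read base lifts ("unliftable").
compose_layout <- function(lay, map) {
  tlift <- rep(NA_integer_, length(lay$cls))
  m <- lay$cls == "M"
  if (any(m)) tlift[m] <- map_lift(map, lay$qpos[m])
  span <- map$query_span
  cls <- lay$cls
  outside <- m & (lay$qpos < span[1L] | lay$qpos >= span[2L])
  cls[outside] <- "S"                       # read ends beyond the map span
  cls[m & !outside & is.na(tlift)] <- "I"   # query-lineage insertion
  lead_h <- lay$lead_h; trail_h <- lay$trail_h
  orig <- lay$cls
  reversed <- map$orientation == "reverse"
  if (reversed) {
    cls <- rev(cls); tlift <- rev(tlift); orig <- rev(orig)
    tmp <- lead_h; lead_h <- trail_h; trail_h <- tmp
  }
  mi <- which(cls == "M")
  if (length(mi) == 0L) return(NULL)
  # emit per-base ops, with D for jumps between consecutive lifted targets
  op <- character(0); len <- integer(0)
  last_t <- NA_integer_
  first_t <- tlift[mi[1L]]
  for (j in seq_along(cls)) {
    if (cls[j] == "M") {
      t <- tlift[j]
      if (!is.na(last_t)) {
        if (t <= last_t)
          stop("internal error: non-increasing target positions in composition")
        if (t - last_t > 1L) { op <- c(op, "D"); len <- c(len, t - last_t - 1L) }
      }
      op <- c(op, "M"); len <- c(len, 1L)
      last_t <- t
    } else {
      op <- c(op, cls[j]); len <- c(len, 1L)
    }
  }
  cc <- cigar_canonical(len, op)
  if (lead_h > 0L) { cc$op <- c("H", cc$op); cc$len <- c(lead_h, cc$len) }
  if (trail_h > 0L) { cc$op <- c(cc$op, "H"); cc$len <- c(cc$len, trail_h) }
  n_lead_s <- sum(cumprod(cls == "S"))
  n_trail_s <- sum(cumprod(rev(cls) == "S"))
  list(target_pos = first_t,
       cigar = cigar_string(cc$len, cc$op),
       clipped_prefix = n_lead_s - sum(cumprod(orig == "S")),
       clipped_suffix = n_trail_s - sum(cumprod(rev(orig) == "S")),
       reversed = reversed)
}

#' Choose the best coordinate map for a read
#'
#' Among maps overlapping the read's query alignment span, picks the one
#' under which the most read-aligned query positions lift to a target
#' position; ties go to the lexicographically smallest gene id. Returns
#' NULL when the best count is below `min_mapped_bases`.
#'
#' @param read One-row SAM record data frame (mapped).
#' @param index A `map_index`.
#' @param min_mapped_bases Minimum liftable read bases (default 1).
#' @return A `coord_map` or NULL.
#' @export
choose_map <- function(read, index, min_mapped_bases = 1L) {
  lay <- read_base_layout(read$pos, read$cigar)
  qp <- lay$qpos[lay$cls == "M"]
  if (length(qp) == 0L) return(NULL)
  cand <- index_overlaps(index, read$rname, min(qp), max(qp) + 1L)
  choose_from_candidates(qp, cand, index$maps, min_mapped_bases)
}

choose_from_candidates <- function(qp, cand, maps, min_mapped_bases) {
  if (length(cand) == 0L) return(NULL)
  counts <- vapply(cand, function(i) sum(!is.na(map_lift(maps[[i]], qp))), 0L)
  gene <- vapply(cand, function(i) maps[[i]]$gene_id, "")
  best <- order(-counts, gene)[1L]
  if (counts[best] < min_mapped_bases) return(NULL)
  maps[[cand[best]]]
}

#' Compose a read alignment with a coordinate map
#'
#' Produces the read's alignment in target coordinates: read bases on
#' lifted query positions emit M; read bases on unlifted positions inside
#' the map span (query-lineage insertions) emit I; jumps between
#' consecutive lifted target positions emit D; the read's own I stays I and
#' its own D survives as the lifted target gap; read bases outside the map
#' span become soft clips. For a reverse-orientation map the result is
#' expressed target-forward: the caller must reverse-complement SEQ,
#' reverse QUAL and toggle the strand bit (the returned CIGAR is already
#' reversed).
#'
#' @param read One-row SAM record data frame (mapped).
#' @param map A `coord_map` overlapping the read.
#' @return A list with `target_pos` (0-based leftmost M base), `cigar`,
#'   `clipped_prefix`/`clipped_suffix` (newly soft-clipped base counts at
#'   the output ends) and `reversed`; or NULL when no read base lifts.
#' @export
compose_cigar <- function(read, map) {
  compose_layout(read_base_layout(read$pos, read$cigar), map)
}

#' Transform one read to target coordinates
#'
#' Unmapped input passes through (RNAME/POS cleared); mapped input with no
#' usable map, or whose composition retains no aligned base, is returned
#' flagged unmapped (0x4, RNAME `*`, POS 0, CIGAR `*`, MAPQ 0); otherwise a
#' target-coordinate record is returned with MAPQ preserved, MD/NM tags
#' dropped (they describe the query-genome alignment), mate fields reset
#' and, on orientation flip, the strand bit toggled and SEQ/QUAL
#' reverse-complemented/reversed.
#'
#' @param read One-row SAM record data frame.
#' @param index A `map_index`.
#' @param min_mapped_bases Minimum liftable read bases (default 1).
#' @return A one-row SAM record data frame.
#' @export
transform_read <- function(read, index, min_mapped_bases = 1L) {
  res <- transform_records(read, index, min_mapped_bases)
  res$records
}

#' Transform a batch of reads
#'
#' Vector version of [transform_read()]; preserves record order.
#'
#' @param records SAM record data frame.
#' @param index A `map_index`.
#' @param min_mapped_bases Minimum liftable read bases.
#' @return A list with `records` (transformed, same row count) and `stats`
#'   (`n_input`, `n_transformed`, `n_unmapped_out`,
#'   `n_passthrough_unmapped`, `per_gene` named counts).
#' @export
transform_records <- function(records, index, min_mapped_bases = 1L) {
  n <- nrow(records)
  # mutate plain column vectors; a data frame is reassembled at the end
  flag <- records$flag; rname <- records$rname; pos <- records$pos
  mapq <- records$mapq; cigar <- records$cigar
  seqv <- records$seq; qualv <- records$qual
  tags <- records$tags
  rnext <- rep("*", n); pnext <- rep(0L, n); tlen <- rep(0L, n)
  genes <- character(0)
  n_transformed <- 0L; n_unmapped_out <- 0L; n_pass <- 0L
  mapped <- is_mapped(records) & !is.na(records$pos) & records$cigar != "*"
  for (i in seq_len(n)) {
    if (!mapped[i]) {
      rname[i] <- "*"; pos[i] <- NA_integer_; cigar[i] <- "*"
      n_pass <- n_pass + 1L
      next
    }
    lay <- read_base_layout(pos[i], cigar[i])
    qp <- lay$qpos[lay$cls == "M"]
    map <- if (length(qp)) {
      cand <- index_overlaps(index, rname[i], min(qp), max(qp) + 1L)
      choose_from_candidates(qp, cand, index$maps, min_mapped_bases)
    } else NULL
    cc <- if (!is.null(map)) compose_layout(lay, map) else NULL
    if (is.null(cc)) {
      flag[i] <- bitwAnd(bitwOr(flag[i], FLAG_UNMAPPED),
                         bitwNot(FLAG_REVERSE + FLAG_PROPER))
      rname[i] <- "*"; pos[i] <- NA_integer_; mapq[i] <- 0L; cigar[i] <- "*"
      tags[i] <- sam_drop_tags(tags[i])
      n_unmapped_out <- n_unmapped_out + 1L
      next
    }
    rname[i] <- map$target_chrom
    pos[i] <- cc$target_pos
    cigar[i] <- cc$cigar
    flag[i] <- bitwAnd(flag[i], bitwNot(FLAG_PROPER))
    if (cc$reversed) {
      flag[i] <- bitwXor(flag[i], FLAG_REVERSE)
      if (seqv[i] != "*") seqv[i] <- revcomp_chr(seqv[i])
      if (qualv[i] != "*") qualv[i] <- reverse_chr(qualv[i])
    }
    tags[i] <- sam_drop_tags(tags[i])
    n_transformed <- n_transformed + 1L
    genes <- c(genes, map$gene_id)
  }
  out <- data.frame(qname = records$qname, flag = flag, rname = rname,
                    pos = pos, mapq = mapq, cigar = cigar, rnext = rnext,
                    pnext = pnext, tlen = tlen, seq = seqv, qual = qualv,
                    tags = tags, stringsAsFactors = FALSE)
  per_gene <- if (length(genes)) table(genes) else table(character(0))
  list(records = out,
       stats = list(n_input = n, n_transformed = n_transformed,
                    n_unmapped_out = n_unmapped_out,
                    n_passthrough_unmapped = n_pass,
                    per_gene = per_gene))
}

combine_stats <- function(stats_list) {
  per_gene_all <- unlist(lapply(stats_list, function(s) s$per_gene))
  per_gene <- if (length(per_gene_all))
    tapply(per_gene_all, names(per_gene_all), sum) else per_gene_all
  list(n_input = sum(vapply(stats_list, `[[`, 0L, "n_input")),
       n_transformed = sum(vapply(stats_list, `[[`, 0L, "n_transformed")),
       n_unmapped_out = sum(vapply(stats_list, `[[`, 0L, "n_unmapped_out")),
       n_passthrough_unmapped =
         sum(vapply(stats_list, `[[`, 0L, "n_passthrough_unmapped")),
       per_gene = per_gene)
}

# Maps derived from the configured gene-alignment SAM (resolving paralogs
# first), unless a maps file already exists.
pipeline_maps <- function(settings) {
  if (!is.null(settings$maps_file) && file.exists(settings$maps_file))
    return(load_maps(settings$maps_file))
  ga <- read_sam(settings$gene_alignment_sam)
  prefs <- if (!is.null(settings$relation_file))
    read_relations(settings$relation_file) else NULL
  res <- resolve_alignments(ga$records, prefs,
                            reciprocal_filter = isTRUE(settings$reciprocal_filter))
  lapply(seq_len(nrow(res$records)), function(i)
    build_coord_map(res$records[i, ]))
}

#' Transform a reads SAM file end to end
#'
#' Reads the configured inputs, lifts every read, and writes the output SAM
#' with `@SQ` lines for every target-genome sequence plus a `@PG` line.
#' Record order equals input order. With `n_jobs > 1` the input is split
#' into contiguous chunks processed in parallel and concatenated in order,
#' so the output is byte-identical to a single-job run.
#'
#' @param settings Settings list from [read_settings()].
#' @param maps Optional list of `coord_map`s; when NULL they are loaded
#'   from `settings$maps_file` if it exists, else computed from the
#'   gene-alignment SAM (applying relation preferences).
#' @return The conversion stats list, invisibly.
#' @export
transform_file <- function(settings, maps = NULL) {
  target <- read_fasta(settings$target_genome)
  if (is.null(maps)) maps <- pipeline_maps(settings)
  index <- build_index(maps)
  input <- read_sam(settings$reads_sam)
  recs <- input$records
  n <- nrow(recs)
  n_jobs <- max(1L, as.integer(settings$n_jobs))
  if (n == 0L) {
    res_records <- recs
    stats <- list(n_input = 0L, n_transformed = 0L, n_unmapped_out = 0L,
                  n_passthrough_unmapped = 0L, per_gene = table(character(0)))
  } else {
    chunks <- parallel::splitIndices(n, min(n_jobs, n))
    worker <- function(ix) transform_records(recs[ix, , drop = FALSE],
                                             index, settings$min_mapped_bases)
    parts <- if (n_jobs > 1L)
      parallel::mclapply(chunks, worker, mc.cores = n_jobs)
    else lapply(chunks, worker)
    err <- vapply(parts, function(p) inherits(p, "try-error") ||
                    is.null(p$records), TRUE)
    if (any(err)) stop("read transformation failed in a worker chunk")
    res_records <- do.call(rbind, lapply(parts, `[[`, "records"))
    stats <- combine_stats(lapply(parts, `[[`, "stats"))
  }
  header <- c("@HD\tVN:1.6",
              paste0("@SQ\tSN:", names(target), "\tLN:",
                     Biostrings::width(target)),
              paste0("@PG\tID:readlift\tPN:readlift\tVN:",
                     as.character(utils::packageVersion("readlift")),
                     "\tCL:readlift convert"))
  write_sam(settings$output_sam, header, res_records)
  message("transformed ", stats$n_transformed, "/", stats$n_input,
          " reads (", stats$n_unmapped_out, " newly unmapped, ",
          stats$n_passthrough_unmapped, " unmapped on input)")
  invisible(stats)
}
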