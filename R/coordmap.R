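# Block-structured query-genome -> target-genome coordinate maps, built by
# walking the CIGAR of a gene-region-to-target alignment. Blocks are stored
# ascending on the query; within a block the query->target function is
# affine (increasing for forward maps, decreasing for reverse maps).

new_coord_map <- function(gene_id, query_chrom, target_chrom, orientation,
                          blocks) {
  rownames(blocks) <- NULL
  n <- nrow(blocks)
  structure(list(gene_id = gene_id, query_chrom = query_chrom,
                 target_chrom = target_chrom, orientation = orientation,
                 blocks = blocks,
                 query_span = c(blocks$query_start[1L],
                                blocks$query_start[n] + blocks$length[n])),
            class = "coord_map")
}

merge_map_blocks <- function(qs, ts, ln, reverse) {
  if (length(qs) <= 1L)
    return(data.frame(query_start = qs, target_start = ts, length = ln))
  step <- if (reverse) -1L else 1L
  mq <- qs[1L]; mt <- ts[1L]; ml <- ln[1L]
  oq <- ot <- ol <- integer(0)
  for (k in 2L:length(qs)) {
    if (qs[k] == mq + ml && ts[k] == mt + step * ml) {
      ml <- ml + ln[k]
    } else {
      oq <- c(oq, mq); ot <- c(ot, mt); ol <- c(ol, ml)
      mq <- qs[k]; mt <- ts[k]; ml <- ln[k]
    }
  }
  data.frame(query_start = c(oq, mq), target_start = c(ot, mt),
             length = c(ol, ml))
}

#' Build a coordinate map from one gene-region alignment
#'
#' Walks the alignment CIGAR: M/=/X runs pair region (query-genome)
#' positions with target positions and become blocks; I/S/H consume region
#' bases without target partners; D/N consume target bases without query
#' partners (N, emitted by spliced aligners for introns, is treated exactly
#' like D). For a reverse-strand alignment the stored SEQ is the reverse
#' complement of the extracted region, so stored offset i corresponds to
#' region offset `region_length - 1 - i` and the map's orientation is
#' `"reverse"`. Adjacent colinear blocks are merged.
#'
#' @param record One-row SAM record data frame (QNAME must be a region
#'   provenance header unless `region` is supplied).
#' @param region Optional region list from [parse_region_header()].
#' @return A `coord_map` object.
#' @export
build_coord_map <- function(record, region = NULL) {
  if (is.null(region)) region <- parse_region_header(record$qname)
  if (bitwAnd(record$flag, FLAG_UNMAPPED) != 0L || is.na(record$pos))
    stop("cannot build a coordinate map from unmapped alignment '",
         record$qname, "'")
  rl <- region$region_end - region$region_start
  cp <- cigar_parse(record$cigar)
  qcons <- sum(cp$len[cp$op %in% c("M", "I", "S", "H", "=", "X")])
  if (qcons != rl)
    stop("alignment '", record$qname, "' accounts for ", qcons,
         " region bases but the region is ", rl, " bases long")
  rev <- bitwAnd(record$flag, FLAG_REVERSE) != 0L
  qs <- ts <- ln <- integer(0)
  t <- record$pos; i <- 0L
  for (k in seq_along(cp$op)) {
    op <- cp$op[k]; n <- cp$len[k]
    if (op %in% c("M", "=", "X")) {
      if (!rev) {
        qs <- c(qs, region$region_start + i); ts <- c(ts, t)
      } else {
        qs <- c(qs, region$region_start + rl - i - n)
        ts <- c(ts, t + n - 1L)
      }
      ln <- c(ln, n); i <- i + n; t <- t + n
    } else if (op %in% c("I", "S", "H")) {
      i <- i + n
    } else if (op %in% c("D", "N")) {
      t <- t + n
    }                                   # P consumes neither
  }
  if (length(qs) == 0L)
    stop("alignment '", record$qname, "' has no aligned bases")
  if (rev) { qs <- rev(qs); ts <- rev(ts); ln <- rev(ln) }
  blocks <- merge_map_blocks(qs, ts, ln, rev)
  new_coord_map(region$gene_id, region$chrom, record$rname,
                if (rev) "reverse" else "forward", blocks)
}

# Lift a vector of query positions through one map; NA where uncovered.
map_lift <- function(map, q) {
  b <- map$blocks
  i <- findInterval(q, b$query_start)
  i0 <- pmax(i, 1L)
  ok <- i >= 1L & q < b$query_start[i0] + b$length[i0]
  off <- q - b$query_start[i0]
  t <- rep(NA_integer_, length(q))
  if (map$orientation == "forward") {
    t[ok] <- b$target_start[i0][ok] + off[ok]
  } else {
    t[ok] <- b$target_start[i0][ok] - off[ok]
  }
  t
}

#' Index coordinate maps for position lookup
#'
#' @param maps List of `coord_map` objects.
#' @return A `map_index` object supporting [lift_position()] and overlap
#'   queries by query chromosome (backed by [IRanges::findOverlaps()]).
#' @export
build_index <- function(maps) {
  if (length(maps) == 0L)
    return(structure(list(maps = list(), tbl = list(), ir = list()),
                     class = "map_index"))
  chrom <- vapply(maps, `[[`, "", "query_chrom")
  d <- data.frame(i = seq_along(maps),
                  start = vapply(maps, function(m) m$query_span[1L], 0L),
                  end = vapply(maps, function(m) m$query_span[2L], 0L))
  tbl <- split(d, chrom)
  ir <- lapply(tbl, function(x) IRanges::IRanges(start = x$start + 1L,
                                                 end = x$end))
  structure(list(maps = maps, tbl = tbl, ir = ir), class = "map_index")
}

# Indices of maps whose query span overlaps [start, end) on chrom.
index_overlaps <- function(index, chrom, start, end) {
  d <- index$tbl[[chrom]]
  if (is.null(d) || end <= start) return(integer(0))
  h <- IRanges::findOverlaps(IRanges::IRanges(start + 1L, end),
                             index$ir[[chrom]])
  sort(d$i[S4Vectors::subjectHits(h)])
}

#' Lift one query-genome position to target coordinates
#'
#' @param index A `map_index`.
#' @param chrom Query chromosome name.
#' @param pos 0-based query position.
#' @return A data frame (`gene_id`, `target_chrom`, `target_pos`,
#'   `orientation`), one row per map pairing `pos` with a target base,
#'   ordered by `gene_id`; zero rows when no map covers `pos` or it falls
#'   in an inter-block gap.
#' @export
lift_position <- function(index, chrom, pos) {
  idx <- index_overlaps(index, chrom, pos, pos + 1L)
  rows <- lapply(idx, function(i) {
    m <- index$maps[[i]]
    t <- map_lift(m, pos)
    if (is.na(t)) return(NULL)
    data.frame(gene_id = m$gene_id, target_chrom = m$target_chrom,
               target_pos = t, orientation = m$orientation,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L)
    return(data.frame(gene_id = character(), target_chrom = character(),
                      target_pos = integer(), orientation = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$gene_id), , drop = FALSE]
}

#' Save / load coordinate maps
#'
#' Line-oriented lossless text format, one block per line:
#' `gene_id  query_chrom  query_start  target_chrom  target_start  length
#' orientation` (tab-separated, 0-based).
#'
#' @param maps List of `coord_map` objects.
#' @param path File path.
#' @return `load_maps` returns the list of maps; `save_maps` returns
#'   `path` invisibly.
#' @export
save_maps <- function(maps, path) {
  lines <- unlist(lapply(maps, function(m) {
    paste(m$gene_id, m$query_chrom, m$blocks$query_start, m$target_chrom,
          m$blocks$target_start, m$blocks$length, m$orientation, sep = "\t")
  }))
  writeLines(if (is.null(lines)) character(0) else lines, path)
  invisible(path)
}

#' @rdname save_maps
#' @export
load_maps <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(list())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (ln in seq_along(parts)) {
    p <- parts[[ln]]
    if (length(p) != 7L)
      stop("maps file '", path, "' line ", ln,
           ": expected 7 tab-separated fields, got ", length(p))
    if (anyNA(suppressWarnings(as.integer(p[c(3L, 5L, 6L)]))))
      stop("maps file '", path, "' line ", ln, ": non-integer coordinate")
    if (!p[7L] %in% c("forward", "reverse"))
      stop("maps file '", path, "' line ", ln,
           ": unknown orientation '", p[7L], "'")
  }
  col <- function(i) vapply(parts, `[[`, "", i)
  d <- data.frame(gene_id = col(1L), query_chrom = col(2L),
                  query_start = as.integer(col(3L)),
                  target_chrom = col(4L),
                  target_start = as.integer(col(5L)),
                  length = as.integer(col(6L)), orientation = col(7L),
                  stringsAsFactors = FALSE)
  lapply(unique(d$gene_id), function(g) {
    dg <- d[d$gene_id == g, , drop = FALSE]
    if (length(unique(dg$query_chrom)) != 1L ||
        length(unique(dg$target_chrom)) != 1L ||
        length(unique(dg$orientation)) != 1L)
      stop("maps file '", path, "': inconsistent blocks for gene '", g, "'")
    dg <- dg[order(dg$query_start), , drop = FALSE]
    new_coord_map(g, dg$query_chrom[1L], dg$target_chrom[1L],
                  dg$orientation[1L],
                  data.frame(query_start = dg$query_start,
                             target_start = dg$target_start,
                             length = dg$length))
  })
}
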