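# Independent brute-force oracles: every coordinate relation is re-derived
# here one base at a time, from expanded per-base CIGAR op vectors, with no
# shared code with the block-structured implementation under test.

# "10S90M" -> c("S" x10, "M" x90)
expand_cigar <- function(cigar) {
  parts <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  unlist(lapply(parts, function(p) {
    n <- as.integer(sub("[MIDNSHP=X]$", "", p))
    rep(substr(p, nchar(p), nchar(p)), n)
  }))
}

# per-base pairs of a read alignment: (stored base index 0-based, ref pos)
oracle_aln_pairs <- function(pos, cigar) {
  b <- integer(0); r <- integer(0)
  i <- 0L; q <- pos
  for (op in expand_cigar(cigar)) {
    if (op %in% c("M", "=", "X")) {
      b <- c(b, i); r <- c(r, q); i <- i + 1L; q <- q + 1L
    } else if (op %in% c("I", "S")) i <- i + 1L
    else if (op %in% c("D", "N")) q <- q + 1L
  }
  data.frame(base = b, ref = r)
}

# per-base (query genome pos, target pos) pairs of a gene-region alignment;
# for reverse alignments stored offset i is region offset region_len-1-i
oracle_gene_pairs <- function(region_start, region_len, pos, cigar, reverse) {
  q <- integer(0); tt <- integer(0)
  i <- 0L; t <- pos
  for (op in expand_cigar(cigar)) {
    if (op %in% c("M", "=", "X")) {
      off <- if (reverse) region_len - 1L - i else i
      q <- c(q, region_start + off); tt <- c(tt, t)
      i <- i + 1L; t <- t + 1L
    } else if (op %in% c("I", "S", "H")) i <- i + 1L
    else if (op %in% c("D", "N")) t <- t + 1L
  }
  d <- data.frame(query = q, target = tt)
  d[order(d$query), , drop = FALSE]
}

# all (query, target) pairs encoded by a coord_map's blocks
oracle_map_pairs <- function(map) {
  d <- do.call(rbind, lapply(seq_len(nrow(map$blocks)), function(k) {
    b <- map$blocks[k, ]
    off <- seq_len(b$length) - 1L
    data.frame(query = b$query_start + off,
               target = if (map$orientation == "forward")
                 b$target_start + off else b$target_start - off)
  }))
  d[order(d$query), , drop = FALSE]
}

# named lookup vector target[as.character(query)] from pair data frame
pairs_lookup <- function(pairs) {
  stats::setNames(pairs$target, as.character(pairs$query))
}

# compose read base->query pairs with query->target pairs into the set of
# (stored read base, target pos) a transformed record must encode
oracle_compose <- function(read_pairs, map_pairs) {
  lut <- pairs_lookup(map_pairs)
  t <- lut[as.character(read_pairs$ref)]
  ok <- !is.na(t)
  data.frame(base = read_pairs$base[ok], target = unname(t[ok]))
}

# swap the two genomes of a coordinate map
invert_map <- function(map) {
  b <- map$blocks
  if (map$orientation == "forward") {
    nb <- data.frame(query_start = b$target_start, target_start = b$query_start,
                     length = b$length)
  } else {
    nb <- data.frame(query_start = b$target_start - b$length + 1L,
                     target_start = b$query_start + b$length - 1L,
                     length = b$length)
  }
  nb <- nb[order(nb$query_start), , drop = FALSE]
  rownames(nb) <- NULL
  readlift:::new_coord_map(map$gene_id, map$target_chrom, map$query_chrom,
                           map$orientation, nb)
}

rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# a random gene-region alignment with matching provenance header
random_gene_aln <- function(chrom = "chrQ", target = "chrT",
                            max_ops = 6L, reverse = NA) {
  region_start <- sample(0:500, 1)
  ops <- c("M", sample(c("M", "I", "D", "S"), sample(0:max_ops, 1),
                       replace = TRUE, prob = c(.5, .2, .2, .1)), "M")
  lens <- sample(1:12, length(ops), replace = TRUE)
  grp <- cumsum(c(TRUE, ops[-1] != ops[-length(ops)]))
  lens <- as.integer(tapply(lens, grp, sum)); ops <- ops[!duplicated(grp)]
  qlen <- sum(lens[ops %in% c("M", "I", "S")])
  pos <- sample(0:500, 1)
  if (is.na(reverse)) reverse <- sample(c(TRUE, FALSE), 1)
  qname <- sprintf("g1::%s:%d-%d(+)", chrom, region_start,
                   region_start + qlen)
  rec <- sam_records(qname = qname, flag = if (reverse) 16L else 0L,
                     rname = target, pos = pos,
                     cigar = paste0(lens, ops, collapse = ""))
  list(record = rec, region_start = region_start, region_len = qlen,
       pos = pos, reverse = reverse)
}

# count disagreements between transformed reads and the truth map; input
# and output records are row-aligned
count_oracle_mismatches <- function(inp, out, truth) {
  mism <- 0L; checked <- 0L
  for (i in seq_len(nrow(out))) {
    if (bitwAnd(out$flag[i], 4L) != 0L) next
    li <- readlift:::read_base_layout(inp$pos[i], inp$cigar[i])
    lo <- readlift:::read_base_layout(out$pos[i], out$cigar[i])
    qp <- li$qpos
    if (bitwAnd(inp$flag[i], 16L) != bitwAnd(out$flag[i], 16L)) qp <- rev(qp)
    j <- which(lo$cls == "M")
    checked <- checked + length(j)
    want <- truth[[inp$rname[i]]][qp[j] + 1L]
    mism <- mism + sum(is.na(want) | want != lo$qpos[j])
  }
  list(checked = checked, mismatches = mism)
}
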