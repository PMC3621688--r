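# Self-contained simulation of a query genome, a mutated sister ("target")
# genome with an exact base-level truth correspondence, planted gene
# annotations, truth-derived gene-region alignments (standing in for an
# external long-sequence aligner) and error-free pre-aligned reads. The
# truth map is the oracle every lifting result is checked against.

.BASES <- c("A", "C", "G", "T")

#' Generate a random genome
#'
#' Uniform i.i.d. bases; bit-reproducible for a fixed seed.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param seed Integer RNG seed.
#' @return A named [Biostrings::DNAStringSet].
#' @export
random_genome <- function(chrom_lengths, seed) {
  set.seed(seed)
  if (length(chrom_lengths) == 0L) return(Biostrings::DNAStringSet())
  stopifnot(all(chrom_lengths >= 1L))
  seqs <- vapply(chrom_lengths, function(L)
    paste(sample(.BASES, L, replace = TRUE), collapse = ""), "")
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(chrom_lengths)
  out
}

#' Mutate a genome, recording the truth correspondence
#'
#' Walks each chromosome left to right drawing one mutually exclusive event
#' per surveyed base: deletion (this and the next `len - 1` bases vanish),
#' insertion (`len` random bases inserted before the surviving base), SNP
#' (base replaced by a different one, coordinates preserved), or identity.
#' Indel lengths are uniform on `[1, max_indel_len]`.
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param snp_rate,ins_rate,del_rate Per-base event probabilities
#'   (`snp_rate + ins_rate + del_rate < 1`).
#' @param max_indel_len Maximum indel length (>= 1).
#' @param seed Integer RNG seed.
#' @return A list with `target` (mutated [Biostrings::DNAStringSet]) and
#'   `truth`: per query chromosome an integer vector giving, for each
#'   0-based query position `p` (element `p + 1`), its 0-based target
#'   position, or NA where the base was deleted.
#' @export
mutate_genome <- function(genome, snp_rate = 0.01, ins_rate = 0.002,
                          del_rate = 0.002, max_indel_len = 10L, seed = 1L) {
  stopifnot(snp_rate + ins_rate + del_rate <= 1, max_indel_len >= 1L,
            snp_rate >= 0, ins_rate >= 0, del_rate >= 0)
  set.seed(seed)
  target <- character(length(genome))
  truth <- vector("list", length(genome))
  names(truth) <- names(genome)
  for (ci in seq_along(genome)) {
    bases <- strsplit(as.character(genome[[ci]]), "", fixed = TRUE)[[1L]]
    n <- length(bases)
    out <- character(n + as.integer(ceiling(n * ins_rate * max_indel_len)) +
                     8L * max_indel_len)
    tpos <- rep(NA_integer_, n)
    i <- 1L; t <- 0L
    while (i <= n) {
      if (t + max_indel_len + 1L > length(out))
        out <- c(out, character(length(out) + 16L * max_indel_len))
      u <- stats::runif(1L)
      if (u < del_rate) {
        i <- i + sample.int(max_indel_len, 1L)
      } else if (u < del_rate + ins_rate) {
        L <- sample.int(max_indel_len, 1L)
        out[t + seq_len(L)] <- sample(.BASES, L, replace = TRUE)
        t <- t + L
        out[t + 1L] <- bases[i]
        tpos[i] <- t; t <- t + 1L; i <- i + 1L
      } else if (u < del_rate + ins_rate + snp_rate) {
        out[t + 1L] <- sample(setdiff(.BASES, bases[i]), 1L)
        tpos[i] <- t; t <- t + 1L; i <- i + 1L
      } else {
        out[t + 1L] <- bases[i]
        tpos[i] <- t; t <- t + 1L; i <- i + 1L
      }
    }
    target[ci] <- paste(out[seq_len(t)], collapse = "")
    truth[[ci]] <- tpos
  }
  tg <- Biostrings::DNAStringSet(target)
  names(tg) <- names(genome)
  list(target = tg, truth = truth)
}

#' Look up the truth correspondence for one position
#'
#' @param truth Truth list from [mutate_genome()].
#' @param chrom Query chromosome name.
#' @param pos 0-based query position.
#' @return The 0-based target position, or NA when the base was deleted.
#' @export
oracle_lift <- function(truth, chrom, pos) {
  tv <- truth[[chrom]]
  if (is.null(tv) || any(pos < 0L) || any(pos >= length(tv)))
    return(NA_integer_)
  tv[pos + 1L]
}

#' Plant non-overlapping gene features on a genome
#'
#' Genes are distributed over chromosomes proportionally to length, with
#' random lengths and strands, separated from each other and from the
#' chromosome ends by at least `flank_gap` bases.
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param n_genes Number of genes.
#' @param length_range Length 2 integer vector, inclusive gene length range.
#' @param flank_gap Minimum separation in bp.
#' @param seed Integer RNG seed.
#' @return A feature data frame in the layout of [read_gff3_genes()].
#' @export
plant_genes <- function(genome, n_genes, length_range = c(500L, 1000L),
                        flank_gap = 1200L, seed = 1L) {
  set.seed(seed)
  empty <- read_gff3_genes_empty()
  if (n_genes == 0L) return(empty)
  lens <- Biostrings::width(genome)
  k <- floor(n_genes * lens / sum(lens))
  while (sum(k) < n_genes) {          # hand remainders to the largest chroms
    j <- order(-(lens - k * mean(length_range)))[1L]
    k[j] <- k[j] + 1L
  }
  rows <- list(); gid <- 0L
  for (ci in seq_along(genome)) {
    if (k[ci] == 0L) next
    gl <- sample(seq(length_range[1L], length_range[2L]), k[ci],
                 replace = TRUE)
    slack <- lens[ci] - sum(gl) - (k[ci] + 1L) * flank_gap
    if (slack < 0L)
      stop("cannot place ", k[ci], " genes of up to ", length_range[2L],
           " bp with gap ", flank_gap, " on a ", lens[ci],
           " bp chromosome")
    extra <- as.vector(stats::rmultinom(1L, slack, rep(1, k[ci] + 1L)))
    cursor <- 0L
    for (j in seq_len(k[ci])) {
      cursor <- cursor + flank_gap + extra[j]
      gid <- gid + 1L
      rows[[gid]] <- data.frame(
        seqid = names(genome)[ci], type = "gene", start = cursor,
        end = cursor + gl[j], strand = sample(c("+", "-"), 1L),
        gene_id = sprintf("g%03d", gid), stringsAsFactors = FALSE)
      cursor <- cursor + gl[j]
    }
  }
  out <- do.call(rbind, rows)
  out$attributes <- lapply(out$gene_id, function(g) c(ID = g))
  out
}

read_gff3_genes_empty <- function() {
  out <- data.frame(seqid = character(), type = character(),
                    start = integer(), end = integer(),
                    strand = character(), gene_id = character(),
                    stringsAsFactors = FALSE)
  out$attributes <- list()
  out
}

#' Exact gene-region alignments from the truth map
#'
#' Stands in for the external long-sequence aligner: for each extracted
#' region the CIGAR is read directly off the truth correspondence — runs of
#' corresponding bases become M, query-only runs I, target-only runs D,
#' and unaligned region ends soft clips. Regions with no corresponding
#' base are omitted. An `AS:i` tag carries the aligned-base count.
#'
#' @param regions Region data frame from [compute_regions()].
#' @param truth Truth list from [mutate_genome()].
#' @param region_seqs Optional [Biostrings::DNAStringSet] of the extracted
#'   region sequences (named by [region_header()]); included as SEQ when
#'   given, else SEQ is `*`.
#' @return A SAM record data frame.
#' @export
truth_alignment_sam <- function(regions, truth, region_seqs = NULL) {
  hdrs <- region_header(regions)
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    chrom <- regions$chrom[i]
    rs <- regions$region_start[i]; re <- regions$region_end[i]
    tv <- truth[[chrom]][(rs + 1L):re]
    nn <- which(!is.na(tv))
    if (length(nn) == 0L) next
    first <- nn[1L]; last <- nn[length(nn)]
    op <- character(0); len <- integer(0)
    if (first > 1L) { op <- "S"; len <- first - 1L }
    prev_t <- NA_integer_
    j <- first
    while (j <= last) {
      if (is.na(tv[j])) {
        r <- j
        while (is.na(tv[r + 1L])) r <- r + 1L
        op <- c(op, "I"); len <- c(len, r - j + 1L)
        j <- r + 1L
      } else {
        if (!is.na(prev_t) && tv[j] - prev_t > 1L) {
          op <- c(op, "D"); len <- c(len, tv[j] - prev_t - 1L)
        }
        op <- c(op, "M"); len <- c(len, 1L)
        prev_t <- tv[j]
        j <- j + 1L
      }
    }
    if (last < length(tv)) { op <- c(op, "S"); len <- c(len, length(tv) - last) }
    cc <- cigar_canonical(len, op)
    seq <- if (!is.null(region_seqs)) as.character(region_seqs[[hdrs[i]]])
           else "*"
    rows[[length(rows) + 1L]] <- sam_records(
      qname = hdrs[i], flag = 0L, rname = chrom, pos = tv[first],
      mapq = 60L, cigar = cigar_string(cc$len, cc$op), seq = seq,
      tags = paste0("AS:i:", length(nn)))
  }
  if (length(rows) == 0L) return(empty_sam_records())
  do.call(rbind, rows)
}

#' Simulate error-free pre-aligned reads
#'
#' Substrings of the query genome with exact all-M alignments; a stated
#' fraction is drawn from outside every region (these must come out
#' unmapped after conversion). Reverse-strand reads are stored
#' reverse-complemented with flag 0x10, as a short-read aligner would
#' report them.
#'
#' @param genome A named [Biostrings::DNAStringSet] (query genome).
#' @param regions Region data frame from [compute_regions()].
#' @param read_length Read length in bp.
#' @param n_reads Number of reads.
#' @param seed Integer RNG seed.
#' @param fraction_outside Fraction of reads placed wholly outside every
#'   region.
#' @return A SAM record data frame.
#' @export
simulate_reads <- function(genome, regions, read_length = 75L,
                           n_reads = 5000L, seed = 1L,
                           fraction_outside = 0) {
  set.seed(seed)
  if (n_reads == 0L) return(empty_sam_records())
  n_out <- as.integer(round(n_reads * fraction_outside))
  inside <- data.frame(chrom = regions$chrom, start = regions$region_start,
                       end = regions$region_end, stringsAsFactors = FALSE)
  if (n_reads - n_out > 0L && nrow(inside) == 0L)
    stop("no regions to draw inside reads from")
  if (any(inside$end - inside$start < read_length))
    stop("read_length exceeds the shortest region")
  # complement of the (merged) regions, per chromosome
  outside <- list()
  for (ci in seq_along(genome)) {
    ch <- names(genome)[ci]
    L <- Biostrings::width(genome)[ci]
    rr <- inside[inside$chrom == ch, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(rr$start + 1L, rr$end))
    gaps <- IRanges::gaps(ir, start = 1L, end = L)
    gd <- data.frame(chrom = ch, start = IRanges::start(gaps) - 1L,
                     end = IRanges::end(gaps), stringsAsFactors = FALSE)
    outside[[ci]] <- gd[gd$end - gd$start >= read_length, , drop = FALSE]
  }
  outside <- do.call(rbind, outside)
  if (n_out > 0L && nrow(outside) == 0L)
    stop("no inter-region space of at least one read length")
  is_out <- sample(c(rep(TRUE, n_out), rep(FALSE, n_reads - n_out)))
  pick <- function(tbl) {
    w <- tbl$end - tbl$start - read_length + 1L
    i <- sample.int(nrow(tbl), 1L, prob = w)
    s <- tbl$start[i] + sample.int(w[i], 1L) - 1L
    c(tbl$chrom[i], s)
  }
  chrom <- character(n_reads); pos <- integer(n_reads)
  for (i in seq_len(n_reads)) {
    p <- pick(if (is_out[i]) outside else inside)
    chrom[i] <- p[[1L]]; pos[i] <- as.integer(p[[2L]])
  }
  strand_rev <- sample(c(TRUE, FALSE), n_reads, replace = TRUE)
  seqs <- as.character(Biostrings::subseq(genome[chrom], start = pos + 1L,
                                          width = read_length))
  seqs[strand_rev] <- vapply(seqs[strand_rev], revcomp_chr, "",
                             USE.NAMES = FALSE)
  sam_records(qname = sprintf("read%05d", seq_len(n_reads)),
              flag = ifelse(strand_rev, FLAG_REVERSE, 0L),
              rname = chrom, pos = pos, mapq = 60L,
              cigar = paste0(read_length, "M"), seq = seqs,
              qual = strrep("I", read_length))
}

#' Simulate a complete cross-species dataset
#'
#' Generates a query genome, its mutated sister genome, planted genes,
#' truth-derived gene-region alignments and pre-aligned reads, and writes
#' the full input set (`query.fa`, `target.fa`, `genes.gff3`, `reads.sam`,
#' `genes_vs_target.sam`, `truth.tsv`, `settings.ini`) to a directory.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed driving every random choice.
#' @param chrom_lengths Named chromosome lengths of the query genome.
#' @param n_genes,gene_length_range,flank_gap Gene-planting parameters.
#' @param snp_rate,ins_rate,del_rate,max_indel_len Mutation model.
#' @param n_reads,read_length,fraction_outside Read simulation parameters.
#' @param flank_upstream,flank_downstream Flanks used for extraction and
#'   recorded in the written `settings.ini`.
#' @return Invisibly, a list with the generated objects (`genome`,
#'   `target`, `truth`, `features`, `regions`, `reads`, `gene_alignments`)
#'   and `settings` (the parsed settings for the written files).
#' @export
simulate_dataset <- function(dir, seed = 42L,
                             chrom_lengths = c(chr1 = 50000L, chr2 = 50000L),
                             n_genes = 20L,
                             gene_length_range = c(500L, 1000L),
                             flank_gap = 1200L,
                             snp_rate = 0.01, ins_rate = 0.002,
                             del_rate = 0.002, max_indel_len = 10L,
                             n_reads = 5000L, read_length = 75L,
                             fraction_outside = 0.1,
                             flank_upstream = 500L,
                             flank_downstream = 500L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genome <- random_genome(chrom_lengths, seed = seed)
  mut <- mutate_genome(genome, snp_rate = snp_rate, ins_rate = ins_rate,
                       del_rate = del_rate, max_indel_len = max_indel_len,
                       seed = seed + 1L)
  features <- plant_genes(genome, n_genes, gene_length_range, flank_gap,
                          seed = seed + 2L)
  regions <- compute_regions(features, flank_upstream, flank_downstream,
                             stats::setNames(Biostrings::width(genome),
                                             names(genome)))
  region_seqs <- extract_sequences(genome, regions)
  gene_aln <- truth_alignment_sam(regions, mut$truth, region_seqs)
  reads <- simulate_reads(genome, regions, read_length = read_length,
                          n_reads = n_reads, seed = seed + 3L,
                          fraction_outside = fraction_outside)
  p <- function(f) file.path(normalizePath(dir), f)
  write_fasta(genome, p("query.fa"))
  write_fasta(mut$target, p("target.fa"))
  write_gff3(features, p("genes.gff3"))
  write_sam(p("reads.sam"),
            c("@HD\tVN:1.6", paste0("@SQ\tSN:", names(genome), "\tLN:",
                                    Biostrings::width(genome))),
            reads)
  write_sam(p("genes_vs_target.sam"),
            c("@HD\tVN:1.6", paste0("@SQ\tSN:", names(mut$target), "\tLN:",
                                    Biostrings::width(mut$target))),
            gene_aln)
  truth_df <- do.call(rbind, lapply(names(mut$truth), function(ch) {
    tv <- mut$truth[[ch]]
    ok <- !is.na(tv)
    data.frame(chrom = ch, query_pos = which(ok) - 1L,
               target_pos = tv[ok], stringsAsFactors = FALSE)
  }))
  utils::write.table(truth_df, p("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(c(
    "[readlift]",
    paste0("reads_sam = ", p("reads.sam")),
    paste0("query_genome = ", p("query.fa")),
    paste0("query_gff3 = ", p("genes.gff3")),
    paste0("target_genome = ", p("target.fa")),
    paste0("gene_alignment_sam = ", p("genes_vs_target.sam")),
    paste0("output_sam = ", p("converted.sam")),
    paste0("regions_fasta = ", p("regions.fa")),
    paste0("maps_file = ", p("maps.txt")),
    paste0("flank_upstream = ", flank_upstream),
    paste0("flank_downstream = ", flank_downstream)),
    p("settings.ini"))
  invisible(list(genome = genome, target = mut$target, truth = mut$truth,
                 features = features, regions = regions,
                 region_seqs = region_seqs, gene_alignments = gene_aln,
                 reads = reads, dir = normalizePath(dir),
                 settings = read_settings(p("settings.ini"))))
}
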