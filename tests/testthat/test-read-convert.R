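# Read transformation: CIGAR composition, map arbitration, unmapped
# semantics, batch/parallel file conversion

map1 <- function() build_coord_map(sam_records(
  qname = "g::chrQ:100-110(+)", rname = "chrT", pos = 50L, cigar = "10M"))
map2 <- function() build_coord_map(sam_records(
  qname = "g::chrQ:100-110(+)", rname = "chrT", pos = 50L, cigar = "4M2D6M"))

read_at <- function(pos, cigar = "10M", seq = strrep("A", 10), flag = 0L,
                    qual = NULL, rname = "chrQ", tags = "") {
  if (is.null(qual)) qual <- strrep("F", nchar(seq))
  sam_records(qname = "r1", flag = flag, rname = rname, pos = pos,
              mapq = 60L, cigar = cigar, seq = seq, qual = qual, tags = tags)
}

test_that("identity composition reproduces the read alignment", {
  cc <- compose_cigar(read_at(100L), map1())
  expect_equal(cc$target_pos, 50L)
  expect_identical(cc$cigar, "10M")
  expect_equal(c(cc$clipped_prefix, cc$clipped_suffix), c(0L, 0L))
})

test_that("target-lineage deletions inside the read become D", {
  cc <- compose_cigar(read_at(100L), map2())
  expect_equal(cc$target_pos, 50L)
  expect_identical(cc$cigar, "4M2D6M")
})

test_that("read bases outside the map span are soft-clipped", {
  cc <- compose_cigar(read_at(96L), map1())
  expect_equal(cc$target_pos, 50L)
  expect_identical(cc$cigar, "4S6M")
  expect_equal(c(cc$clipped_prefix, cc$clipped_suffix), c(4L, 0L))
  # against the two-block map the tail also jumps over the deletion
  cc2 <- compose_cigar(read_at(96L), map2())
  want <- oracle_compose(oracle_aln_pairs(96L, "10M"), oracle_map_pairs(map2()))
  expect_identical(cc2$cigar, "4S4M2D2M")
  got <- oracle_aln_pairs(cc2$target_pos, sub("^4S", "", cc2$cigar))
  got$base <- got$base + 4L           # account for the leading clip
  expect_equal(got$ref, want$target)
  expect_equal(got$base, want$base)
})

test_that("query-lineage insertions in the map emit I inside the read", {
  # map with a 2-base query gap: region [100,112), CIGAR 4M2I6M
  m <- build_coord_map(sam_records(qname = "g::chrQ:100-112(+)",
                                   rname = "chrT", pos = 50L,
                                   cigar = "4M2I6M"))
  cc <- compose_cigar(read_at(100L, "12M", seq = strrep("A", 12)), m)
  expect_identical(cc$cigar, "4M2I6M")
  expect_equal(cc$target_pos, 50L)
})

test_that("composition equals the brute-force per-base oracle on random instances", {
  set.seed(41)
  for (i in 1:200) {
    g <- random_gene_aln()
    m <- build_coord_map(g$record)
    span <- m$query_span
    rlen <- sample(4:15, 1)
    rpos <- sample(max(0, span[1] - 5):(span[2] + 2), 1)
    ops <- c("M", sample(c("M", "I", "D"), sample(0:3, 1), replace = TRUE), "M")
    lens <- sample(1:5, length(ops), replace = TRUE)
    cigar <- paste0(lens, ops, collapse = "")
    qlen <- sum(lens[ops %in% c("M", "I")])
    rd <- read_at(rpos, cigar, seq = strrep("A", qlen), rname = "chrQ")
    cc <- compose_cigar(rd, m)
    want <- oracle_compose(oracle_aln_pairs(rpos, cigar), oracle_map_pairs(m))
    if (is.null(cc)) {
      expect_equal(nrow(want), 0L)
      next
    }
    got <- oracle_aln_pairs(cc$target_pos, cc$cigar)
    if (cc$reversed) got$base <- qlen - 1L - got$base
    got <- got[order(got$base), ]
    want <- want[order(want$base), ]
    expect_equal(got$base, want$base)
    expect_equal(got$ref, want$target)
  }
})

test_that("choose_map maximizes liftable bases, then smallest gene id", {
  mA <- build_coord_map(sam_records(qname = "g2::chrQ:100-140(+)",
                                    rname = "chrT", pos = 0L, cigar = "40M"))
  mB <- build_coord_map(sam_records(qname = "g1::chrQ:125-165(+)",
                                    rname = "chrT", pos = 500L, cigar = "40M"))
  idx <- build_index(list(mA, mB))
  rd <- read_at(105L, "40M", seq = strrep("A", 40))   # 35 bases on g2, 15 on g1
  expect_identical(choose_map(rd, idx)$gene_id, "g2")
  expect_null(choose_map(read_at(300L), idx))
  expect_null(choose_map(read_at(105L, "40M", seq = strrep("A", 40)), idx,
                         min_mapped_bases = 36L))
  # exact tie -> lexicographically smallest gene id
  mC <- build_coord_map(sam_records(qname = "g0::chrQ:100-140(+)",
                                    rname = "chrT2", pos = 900L, cigar = "40M"))
  idx2 <- build_index(list(mA, mC))
  expect_identical(choose_map(rd, idx2)$gene_id, "g0")
})

test_that("transform_read handles passthrough, unliftable and reverse cases", {
  idx <- build_index(list(map1()))
  # unmapped input passes through with placeholders
  un <- sam_records(qname = "u", flag = 4L, seq = "ACGT", qual = "FFFF")
  out <- transform_read(un, idx)
  expect_equal(out$flag, 4L)
  expect_identical(out$rname, "*")
  # read with no covering map comes out flagged unmapped
  rd <- read_at(300L, tags = "NM:i:0\tRG:Z:lib1")
  out <- transform_read(rd, idx)
  expect_equal(bitwAnd(out$flag, 4L), 4L)
  expect_identical(c(out$rname, out$cigar), c("*", "*"))
  expect_true(is.na(out$pos))
  expect_equal(out$mapq, 0L)
  # reverse map: strand toggled, SEQ reverse-complemented, QUAL reversed
  mrev <- build_coord_map(sam_records(qname = "g::chrQ:100-110(+)",
                                      rname = "chrT", pos = 50L,
                                      cigar = "10M", flag = 16L))
  rd <- read_at(100L, seq = "ACGTTGCAAC", qual = "ABCDEFGHIJ",
                tags = "MD:Z:10\tNM:i:0\tRG:Z:lib1")
  out <- transform_read(rd, build_index(list(mrev)))
  expect_equal(bitwAnd(out$flag, 16L), 16L)
  expect_identical(out$seq, rc("ACGTTGCAAC"))
  expect_identical(out$qual, "JIHGFEDCBA")
  expect_equal(out$pos, 50L)
  # MD/NM dropped, other tags preserved; mate fields reset
  expect_identical(out$tags, "RG:Z:lib1")
  expect_identical(out$rnext, "*")
})

test_that("reverse-orientation lifting round-trips through the inverse map", {
  set.seed(51)
  n_fail <- 0L
  for (i in 1:1000) {
    # query-contiguous map (target-lineage indels only), both orientations
    ops <- c("M", sample(c("M", "D"), sample(0:3, 1), replace = TRUE), "M")
    lens <- sample(2:9, length(ops), replace = TRUE)
    qlen <- sum(lens[ops == "M"])
    rs <- sample(0:300, 1)
    reverse <- i %% 2L == 0L
    m <- build_coord_map(sam_records(
      qname = sprintf("g::chrQ:%d-%d(+)", rs, rs + qlen),
      flag = if (reverse) 16L else 0L, rname = "chrT",
      pos = sample(0:300, 1), cigar = paste0(lens, ops, collapse = "")))
    inv <- invert_map(m)
    rlen <- sample(3:min(8, qlen), 1)
    rpos <- rs + sample(0:(qlen - rlen), 1)
    seq <- paste(sample(c("A", "C", "G", "T"), rlen, replace = TRUE),
                 collapse = "")
    rd <- read_at(rpos, paste0(rlen, "M"), seq = seq,
                  flag = sample(c(0L, 16L), 1))
    fwd <- transform_read(rd, build_index(list(m)))
    back <- transform_read(fwd, build_index(list(inv)))
    ok <- identical(back$pos, rd$pos) && identical(back$cigar, rd$cigar) &&
      identical(back$seq, rd$seq) && identical(back$flag, rd$flag) &&
      identical(back$rname, rd$rname)
    n_fail <- n_fail + !ok
  }
  expect_equal(n_fail, 0L)
})

test_that("transform_file writes target @SQ headers and conserves records", {
  dir <- withr::local_tempdir()
  d <- simulate_dataset(dir, seed = 7, chrom_lengths = c(chr1 = 12000L),
                        n_genes = 4L, n_reads = 150L, fraction_outside = 0.2)
  stats <- transform_file(d$settings)
  expect_equal(stats$n_input, 150L)
  expect_equal(stats$n_transformed + stats$n_unmapped_out +
                 stats$n_passthrough_unmapped, stats$n_input)
  out <- read_sam(d$settings$output_sam)
  expect_equal(nrow(out$records), 150L)
  sq <- out$header[startsWith(out$header, "@SQ")]
  expect_identical(sq, paste0("@SQ\tSN:", names(d$target), "\tLN:",
                              Biostrings::width(d$target)))
  expect_true(any(startsWith(out$header, "@PG")))
  # output CIGARs are consistent with SEQ lengths (validated on re-read)
  expect_silent(readlift:::validate_sam_records(out$records))
})

test_that("chunked parallel conversion is byte-identical to serial", {
  dir <- withr::local_tempdir()
  d <- simulate_dataset(dir, seed = 8, chrom_lengths = c(chr1 = 12000L),
                        n_genes = 4L, n_reads = 200L, fraction_outside = 0.1)
  s1 <- d$settings
  s1$output_sam <- file.path(dir, "out1.sam")
  transform_file(s1)
  s4 <- d$settings
  s4$n_jobs <- 4L
  s4$output_sam <- file.path(dir, "out4.sam")
  transform_file(s4)
  expect_identical(readLines(s4$output_sam), readLines(s1$output_sam))
})

test_that("an empty reads file yields a header-only SAM and zero stats", {
  dir <- withr::local_tempdir()
  d <- simulate_dataset(dir, seed = 9, chrom_lengths = c(chr1 = 9000L),
                        n_genes = 2L, n_reads = 10L)
  writeLines("@HD\tVN:1.6", d$settings$reads_sam)
  stats <- transform_file(d$settings)
  expect_equal(stats$n_input, 0L)
  out <- read_sam(d$settings$output_sam)
  expect_equal(nrow(out$records), 0L)
  expect_true(length(out$header) > 0L)
})
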