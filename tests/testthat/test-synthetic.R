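# Simulation harness: genome generation, mutation with exact truth
# correspondence, gene planting, truth alignments, read simulation

test_that("random genomes are seed-reproducible and seed-sensitive", {
  a <- random_genome(c(chr1 = 1000L), seed = 1)
  b <- random_genome(c(chr1 = 1000L), seed = 1)
  expect_identical(as.character(a), as.character(b))
  c <- random_genome(c(chr1 = 1000L), seed = 2)
  expect_false(identical(as.character(a), as.character(c)))
  expect_length(random_genome(integer(0), seed = 1), 0L)
})

test_that("zero mutation rates give an identical genome and identity truth", {
  g <- random_genome(c(chr1 = 500L, chr2 = 300L), seed = 3)
  m <- mutate_genome(g, snp_rate = 0, ins_rate = 0, del_rate = 0, seed = 3)
  expect_identical(as.character(m$target), as.character(g))
  expect_equal(m$truth$chr1, 0:499)
  expect_equal(m$truth$chr2, 0:299)
})

test_that("full deletion of a 1-base genome leaves an empty chromosome", {
  g <- Biostrings::DNAStringSet(c(chr1 = "A"))
  m <- mutate_genome(g, snp_rate = 0, ins_rate = 0, del_rate = 1,
                     max_indel_len = 1L, seed = 1)
  expect_equal(Biostrings::width(m$target), 0L)
  expect_true(all(is.na(m$truth$chr1)))
})

test_that("SNP-only mutation preserves every coordinate", {
  g <- random_genome(c(chr1 = 10000L), seed = 4)
  m <- mutate_genome(g, snp_rate = 0.01, ins_rate = 0, del_rate = 0, seed = 4)
  expect_equal(m$truth$chr1, 0:9999)
  expect_equal(Biostrings::width(m$target), 10000L)
  expect_false(identical(as.character(m$target), as.character(g)))
})

test_that("the truth map is monotone, injective and base-consistent", {
  g <- random_genome(c(chr1 = 20000L), seed = 5)
  m <- mutate_genome(g, seed = 5)   # default rates
  tv <- m$truth$chr1
  surv <- tv[!is.na(tv)]
  expect_false(any(duplicated(surv)))
  expect_true(all(diff(surv) > 0))
  expect_true(max(surv) < Biostrings::width(m$target)[1])
  # most surviving bases are unchanged (SNP rate is 1%)
  qb <- strsplit(as.character(g[[1]]), "")[[1]][!is.na(tv)]
  tb <- strsplit(as.character(m$target[[1]]), "")[[1]][surv + 1L]
  expect_gt(mean(qb == tb), 0.95)
})

test_that("planted genes are disjoint, separated and reproducible", {
  g <- random_genome(c(chr1 = 10000L), seed = 6)
  expect_equal(nrow(plant_genes(g, 0L, seed = 6)), 0L)
  f <- plant_genes(g, 3L, length_range = c(500L, 1000L), flank_gap = 1200L,
                   seed = 6)
  expect_equal(nrow(f), 3L)
  expect_true(all(f$start[-1] - f$end[-3] >= 1200L))
  expect_true(f$start[1] >= 1200L && f$end[3] <= 10000L - 1200L)
  f2 <- plant_genes(g, 3L, length_range = c(500L, 1000L), flank_gap = 1200L,
                    seed = 6)
  expect_identical(f, f2)
  expect_error(plant_genes(g, 50L, length_range = c(500L, 1000L),
                           flank_gap = 1200L, seed = 6), "cannot place")
})

test_that("truth alignments read their CIGAR off the correspondence", {
  regions <- data.frame(gene_id = "g1", chrom = "chr1", gene_start = 10L,
                        gene_end = 30L, strand = "+", region_start = 10L,
                        region_end = 30L, stringsAsFactors = FALSE)
  ident <- list(chr1 = 0:99)
  rec <- truth_alignment_sam(regions, ident)
  expect_identical(rec$cigar, "20M")
  expect_equal(rec$pos, 10L)
  # a 2-base deletion inside the region: aM2DbM with a+b = region length
  tv <- 0:99; tv[21:22] <- NA; tv[23:100] <- tv[23:100] - 2L
  # rebuild as a proper truth vector: positions 20,21 (0-based) deleted
  tv <- ifelse(is.na(tv), NA_integer_, as.integer(tv))
  rec2 <- truth_alignment_sam(regions, list(chr1 = tv))
  expect_identical(rec2$cigar, "10M2I8M")
  # deleted *target* bases instead: truth skips 2 target positions
  tv3 <- c(0:14, 17:101)
  rec3 <- truth_alignment_sam(regions, list(chr1 = tv3))
  expect_identical(rec3$cigar, "5M2D15M")
  # region fully deleted -> omitted
  allna <- list(chr1 = rep(NA_integer_, 100))
  expect_equal(nrow(truth_alignment_sam(regions, allna)), 0L)
})

test_that("simulated reads land inside/outside regions as requested", {
  g <- random_genome(c(chr1 = 10000L), seed = 9)
  f <- plant_genes(g, 3L, length_range = c(500L, 800L), flank_gap = 1200L,
                   seed = 9)
  regions <- compute_regions(f, 200L, 200L, c(chr1 = 10000L))
  inside <- function(r) {
    any(r$pos >= regions$region_start &
        r$pos + 75L <= regions$region_end)
  }
  rin <- simulate_reads(g, regions, n_reads = 100L, seed = 9,
                        fraction_outside = 0)
  expect_equal(nrow(rin), 100L)
  expect_true(all(vapply(seq_len(100), function(i) inside(rin[i, ]), TRUE)))
  rout <- simulate_reads(g, regions, n_reads = 100L, seed = 9,
                         fraction_outside = 1)
  expect_false(any(vapply(seq_len(100), function(i) inside(rout[i, ]), TRUE)))
  # reproducible; stored sequence matches the genome (modulo strand)
  expect_identical(simulate_reads(g, regions, n_reads = 100L, seed = 9,
                                  fraction_outside = 0), rin)
  chr <- as.character(g[[1]])
  for (i in 1:20) {
    sub <- substr(chr, rin$pos[i] + 1L, rin$pos[i] + 75L)
    if (bitwAnd(rin$flag[i], 16L) == 16L) sub <- rc(sub)
    expect_identical(rin$seq[i], sub)
  }
})

test_that("every covered map position agrees with the truth oracle", {
  dir <- withr::local_tempdir()
  d <- simulate_dataset(dir, seed = 13, chrom_lengths = c(chrA = 8000L),
                        n_genes = 3L, n_reads = 10L)
  res <- resolve_alignments(d$gene_alignments)
  maps <- lapply(seq_len(nrow(res$records)), function(i)
    build_coord_map(res$records[i, ]))
  idx <- build_index(maps)
  for (m in maps) {
    p <- oracle_map_pairs(m)
    for (k in seq_len(nrow(p))) {
      expect_identical(oracle_lift(d$truth, m$query_chrom, p$query[k]),
                       p$target[k])
    }
    # and positions the oracle deletes are not covered by the map
    span <- m$query_span[1]:(m$query_span[2] - 1L)
    deleted <- span[is.na(d$truth[[m$query_chrom]][span + 1L])]
    expect_false(any(deleted %in% p$query))
  }
})

test_that("simulate_dataset writes a complete, parseable input set", {
  dir <- withr::local_tempdir()
  d <- simulate_dataset(dir, seed = 14, chrom_lengths = c(chr1 = 9000L),
                        n_genes = 2L, n_reads = 20L)
  for (f in c("query.fa", "target.fa", "genes.gff3", "reads.sam",
              "genes_vs_target.sam", "truth.tsv", "settings.ini"))
    expect_true(file.exists(file.path(dir, f)))
  expect_equal(nrow(read_gff3_genes(file.path(dir, "genes.gff3"))), 2L)
  expect_equal(nrow(read_sam(file.path(dir, "reads.sam"))$records), 20L)
  tt <- utils::read.table(file.path(dir, "truth.tsv"), header = TRUE,
                          sep = "\t")
  i <- sample(nrow(tt), 5)
  expect_equal(oracle_lift(d$truth, "chr1", tt$query_pos[i]) |> unname(),
               tt$target_pos[i])
})
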