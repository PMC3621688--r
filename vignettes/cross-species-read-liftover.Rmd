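---
title: "Cross-species liftover of aligned sequencing reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species liftover of aligned sequencing reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readlift)
```

## The problem

Comparative ChIP-seq and RNA-seq ask whether a signal observed in one
species — a transcription-factor binding site, an expression peak — is
conserved in a relative. Two species' genomes use different coordinate
systems, so the reads of the *query* species (the one sequenced) must be
re-expressed in the coordinates of the *target* species before the two
experiments can be viewed side by side in a genome browser. Re-aligning
the reads directly to the target genome is fragile exactly where it
matters: polymorphisms at the interesting sites degrade or prevent the
short-read alignment. Classic annotation liftover tools convert BED-style
intervals, not SAM records, and cannot re-express a read's CIGAR.

`readlift` takes the indirect route: align a modest number of long
sequences (gene regions with flanks) between the genomes once, turn those
alignments into base-level coordinate maps, and push every read through
the maps. The output is plain SAM against the target genome's sequence
dictionary, so any browser that displays sequencing data can show it.

## Pipeline

1. **Extract** (`compute_regions()`, `extract_sequences()`): each
   annotated gene is extended by an upstream flank 5′ of the
   transcription start site and a downstream flank 3′ of the gene end
   (strand-aware; both default to 500 bp) and the forward-strand genomic
   substring is written as FASTA. The FASTA id encodes provenance:
   `<gene_id>::<chrom>:<start>-<end>(<strand>)`, 0-based half-open.
2. **Align (external)**: the region FASTA is aligned to the target genome
   with a long-sequence aligner (GMAP; BLAST/BLAT after conversion to
   SAM). This step is deliberately outside the package: it is an input
   contract, and `run-all` halts with an explicit message when the
   alignment file is missing.
3. **Resolve** (`resolve_alignments()`): paralogy makes gene-to-target
   alignments one-to-many. Per gene, candidates are filtered by optional
   user preferences (a two-column TSV of gene → `seq` or
   `seq:start-end`), then the best survivor is kept by alignment score.
4. **Combine** (`build_coord_map()`, `save_maps()`): each resolved
   alignment's CIGAR is walked into a list of colinear blocks pairing
   query-genome positions with target-genome positions.
5. **Convert** (`transform_file()`): every read's alignment is composed
   with the best covering map; reads on non-corresponding positions are
   flagged unmapped.

## Coordinate conventions

Internally every coordinate is 0-based half-open. GFF3 (1-based
inclusive) and SAM POS (1-based) are converted exactly once, at the
parse/serialize boundary; no other function performs ±1 arithmetic. This
removes the classic off-by-one family of liftover bugs at its source.

Extracted regions are *always* forward-strand genomic sequence, even for
minus-strand genes; the gene strand is recorded in the header only for
provenance. The aligner reports orientation per alignment, so the strand
algebra of the whole pipeline reduces to a single flag: a reverse-strand
gene alignment means stored sequence offset $i$ corresponds to region
offset $L - 1 - i$ (for region length $L$), and the resulting map is
marked `reverse`. With that convention a map block is fully described by
`(query_start, target_start, length)` and the lift is affine:

$$t(q) = \mathrm{target\_start} \pm (q - \mathrm{query\_start})$$

with $+$ for forward and $-$ for reverse maps. Blocks are stored rather
than per-base pairs because runs of matched bases are contiguous; the
block form is lossless and orders of magnitude smaller.

## CIGAR composition

A read's SAM record encodes a map read base → query position; a
coordinate map encodes query position → target position. Their
composition is emitted left to right over the read bases (after reversing
everything when the map orientation is reverse):

* a read base aligned to a lifted query position emits `M`;
* a read base aligned to a query position inside the map span that lifts
  to nothing (an insertion in the query lineage) emits `I`;
* a jump between the target positions of consecutive `M` bases emits a
  `D` of the jump size — this uniformly covers both target-lineage
  insertions between blocks and the read's own deletions;
* read bases aligned outside the map span become soft clips, and
  existing soft clips stay soft clips;
* the result is canonicalized (adjacent same-code runs merged).

When no read base lifts, or fewer than `min_mapped_bases` (default 1) do,
the read is emitted unmapped: flag 0x4 set, RNAME `*`, POS 0, CIGAR `*`,
MAPQ 0. On orientation flip the strand bit is toggled, SEQ
reverse-complemented and QUAL reversed, so the record is valid
target-forward SAM. MD and NM tags are dropped rather than recomputed:
they describe mismatches against the *query* genome and would be wrong in
target coordinates; recomputing them would require re-reading the target
sequence, which is out of scope. Mate fields are reset (`RNEXT *`,
`PNEXT 0`, `TLEN 0`) and the proper-pair bit cleared on every output
record, because the two mates of a pair may lift through different genes
or not at all; reconstructing cross-species pairing is deliberately not
attempted.

Reads overlapping several gene regions are arbitrated by the map that
lifts the most read bases, ties broken by smallest gene id — a
deterministic rule favouring the better explanation.

## Paralog resolution rules

Selection is a total order: score (the SAM `AS:i` tag when present,
otherwise the count of aligned read bases, which keeps score-less
BLAT-derived SAM usable), then smallest target sequence name, then
smallest target start, then input order. Totality makes the result
invariant under permutation of the input — a property the test suite
checks exhaustively on constructed instances. An optional reciprocal
filter additionally removes lower-ranked genes whose target spans overlap
a kept gene's span by more than 50% of the shorter span, so no target
region keeps two genes. The 50% threshold is a design choice: a
symmetric, scale-free criterion that is deterministic and testable.

## The synthetic harness and what it shows

`simulate_dataset()` builds both sides of the comparison from scratch: a
uniform random query genome; a sister genome derived by per-base
mutually exclusive SNP/insertion/deletion events (indel lengths uniform
on 1–`max_indel_len`), recording the exact surviving-base correspondence
(the *truth map*); non-overlapping planted genes with random strands;
gene-region alignments whose CIGARs are read directly off the truth map
(standing in for the external aligner, exact by construction); and
error-free pre-aligned reads, a chosen fraction placed wholly outside
every region to exercise the unmapped path.

Defaults are two 50 kb chromosomes, 20 genes of 500–1000 bp separated by
at least 1.2 kb (so 500 bp flanked regions never overlap), SNP rate 0.01
and insertion/deletion rates 0.002 each with indels up to 10 bp —
polymorphism densities in the range of closely related fruit-fly species,
whose divergence motivates this kind of comparison — and 5000 reads of
75 bp, 10% outside regions. These sizes give every stage thousands of
informative bases while keeping a full run in seconds.

The truth map is the oracle: for every transformed read, every aligned
base's target position must equal the truth correspondence of the query
base it came from, with zero tolerance. The harness deliberately omits
sequencing errors, quality-score models, spliced genes and structural
rearrangements (inversions, translocations); passing tests therefore
demonstrate the correctness of the coordinate algebra, not robustness to
misalignment in real data, where the quality of the external long-sequence
alignment bounds the quality of the liftover.

## Numerical and degenerate-input choices

* Flank truncation at chromosome ends is silent clamping, as in
  comparable interval liftover tools.
* Unstranded (`.`) features are treated as `+` with a warning: a
  deterministic fallback beats failure on sloppy annotations.
* `N` CIGAR operations are treated exactly as `D`: spliced aligners emit
  `N` for introns, and for coordinate lifting the distinction carries no
  information.
* Soft and hard clips on the gene alignment simply shrink the covered
  span — flanks may legitimately fail to align.
* Genomes without an assembly are supported implicitly: any FASTA works
  as the "genome", including transcriptome-assembly contigs treated as
  one chromosome each.
* Parallelism (`n_jobs`) splits the reads into contiguous chunks
  processed independently and concatenated in order, so output is
  byte-identical to a serial run; a job-scheduler integration is
  intentionally replaced by this local, dependency-free mechanism.
* GFF3 feature selection is a configuration option (`feature_type`,
  default `"gene"`) rather than a guess, since annotations differ in
  whether gene or mRNA rows carry the regions of interest.

## Known limitations

One map per read: a read straddling two adjacent gene maps is not split.
At most one target per gene survives resolution; genuinely duplicated
loci are better served by restricting the relation preference table per
gene. Output is unsorted SAM (input order); sort and index downstream if
a browser requires it.
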