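Package: readlift
Title: Cross-Species Coordinate Transformation of Aligned Sequencing Reads
Version: 0.1.0
Authors@R: person("Readlift", "Developers", email = "readlift@example.org",
    role = c("aut", "cre"))
Description: Transforms the mapping coordinates of next-generation
    sequencing reads (SAM) from the genome of a query species to that of a
    related target species, using alignments of extracted flanked gene
    regions as the coordinate bridge. Includes strand-aware gene-region
    extraction from GFF3 annotation, paralog disambiguation of
    gene-to-target alignments, block-structured coordinate maps with
    interval-indexed lookup, CIGAR-level read re-expression in target
    coordinates (reads on non-corresponding positions are flagged
    unmapped), a fully synthetic simulation harness with an exact
    base-level truth correspondence, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    parallel,
    stats,
    utils
Suggests:
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
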