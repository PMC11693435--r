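Package: isoclass
Title: Structural Classification and Cross-Group Comparison of Long-Read
    RNA Isoforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies long-read transcript models against a reference
    annotation into SQANTI-style structural categories (full splice match,
    incomplete splice match, novel in catalog, novel not in catalog),
    annotates novel-not-in-catalog isoforms with seven splice-level
    features (alternative donor/acceptor junctions, intra-exonic junctions
    including exitrons, partial intron retention, novel exons) under CDS-
    and exon-priority rules for multi-transcript genes and a dedicated
    single-exon-gene rule, and compares isoform usage across samples, cell
    types and condition groups: proportions, major-isoform switching,
    group intersections, and one-way ANOVA with Sidak correction. Includes
    a deterministic synthetic fixture generator for end-to-end validation
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
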