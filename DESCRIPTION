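Package: poplinc
Title: Discovery of Long Intergenic Non-Coding RNAs from Two-Condition RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for identifying long intergenic non-coding
    RNAs (lincRNAs) from aligned RNA-seq reads in two conditions (control and
    drought). Builds per-base coverage, calls transcription active regions,
    links them into gene models with mate-pair evidence, classifies intergenic
    transcription units, and applies a four-filter cascade (length, longest
    ORF, presence in both libraries, similarity to repeat and miRNA-precursor
    libraries) to nominate lincRNA candidates. Candidates are assessed with a
    transparent coding-potential score, tested for differential expression
    with the classical two-library read-count test of Audic and Claverie, and
    scanned for miRNA cleavage targets and endogenous target mimics. A
    synthetic-data module generates toy genomes, annotations, and paired-end
    alignments with a complete ground-truth manifest so every stage is
    verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    igraph,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    GenomicAlignments,
    Rsamtools,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
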