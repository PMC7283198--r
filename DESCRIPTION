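Package: nanotx
Title: Stranded Long-Read cDNA Transcriptome Reconstruction and Isoform Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for processing full-length cDNA long reads from nanopore
    sequencing: recovery of read orientation from terminal poly(A)/poly(T)
    tails, genome-guided transcript reconstruction from per-strand coverage
    and transcript end-site profiles, alternative splicing and UTR isoform
    profiling with upstream-ORF detection, strand-aware gene quantification,
    and sensitivity/specificity assessment of reconstructed transcriptomes.
    Includes a deterministic simulator of toy genomes and stranded
    full-length reads with ground truth, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    methods,
    Rsamtools,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
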