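Package: fldseg
Title: Multipartite dsRNA Virus Genome Reconstruction from FLDS Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs and characterizes complete multipartite
    double-stranded RNA (dsRNA) virus genomes from FLDS libraries
    (fragmented dsRNA with an adaptor ligated to fragment 3' ends).
    Adaptor-bearing read pile-ups call terminal completeness of assembled
    contigs; conserved terminal sequences group full-length segments into
    multipartite genome sets; a deterministic ORF scanner with
    Shine-Dalgarno motif detection and a Kyte-Doolittle hydropathy scan
    annotates segments; six-frame stop-codon maps and trinucleotide
    composition contrasts diagnose long noncoding 5'UTRs; FPKM tables
    summarize virome community composition; and consensus-expansion with
    gap/homogeneity column trimming prepares family-level protein
    alignments for RdRP phylogenetics. A seeded synthetic-data generator
    emulates bisegmented genomes and FLDS reads with ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    rlang,
    readr,
    ggplot2,
    yaml,
    generics,
    withr,
    igraph,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
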