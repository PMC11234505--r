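Package: proseqkit
Title: Preparation and Evolutionary-Genetic Analysis of DNA Polymorphism Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scriptable engine for multi-locus DNA polymorphism studies:
    reconstruction of per-contig sequence alignments from multisample VCF
    files, annotation import (GFF/BED/CSV), alignment preparation (site
    filtering, translation, open-reading-frame search, quality-control
    reports), diversity and subdivision statistics (segregating sites,
    nucleotide diversity, Watterson's theta, Tajima's D, Kelly's ZnS, Fst,
    Kst, permutation tests), sliding-window scans directly on alignments or
    VCF streams, neighbour-joining phylogenies with number-of-differences,
    Jukes-Cantor or Kimura two-parameter distances, and a structured
    coalescent simulator (stepwise size change, island-model subdivision,
    population joins) that produces genealogies, simulated alignments and
    empirical critical values for test statistics. Command-line entry
    points are provided for pipeline use.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    S4Vectors,
    BiocGenerics,
    GenomicRanges,
    vcfR,
    rtracklayer,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
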