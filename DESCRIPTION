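Package: homeolocus
Title: Locus-Specific Sequence Isolation and Genome-Specific Assay Design
    for Allopolyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Isolates subgenome-specific (locus-specific) sequences from
    allopolyploid genomes such as bread wheat. Chains local homology hits
    between gene queries and genome contigs into putative homoeologous gene
    loci under intron/exon length constraints, extracts the loci with
    flanking sequence, multiple-aligns the homoeolog sets with a progressive
    aligner, detects subgenome-diagnostic SNP and indel columns, and designs
    genome-specific PCR primer pairs, CAPS restriction markers, and
    conserved regions for qPCR. Designs are validated by in-silico PCR. A
    simulator generates allopolyploid test genomes with full ground truth so
    the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
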