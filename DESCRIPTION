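Package: npannotate
Title: Homology-Seeded Neuropeptide Annotation for Draft Insect Genomes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies neuropeptide precursor genes in draft insect genome
    annotations by homology search against seed sequences (mature peptides,
    precursors, cDNAs) across three gene-model sets, applies tiered coverage
    acceptance criteria, rescues mis-framed open reading frames by six-frame
    re-translation, verifies genomic loci by translation identity of spliced
    CDS regions, merges accepted models into the draft GFF3/FASTA with new
    locus identifiers, and validates annotations by z-score normalised
    expression profiles with hierarchical clustering. Ships a synthetic
    genome generator with planted neuropeptide genes so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    pheatmap,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
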