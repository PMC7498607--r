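Package: ssrminer
Title: Genome-Wide Microsatellite Mining and Marker Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for genome-wide discovery of microsatellites (simple
    sequence repeats, SSRs) and development of SSR markers from assembled
    genomes. Scans FASTA assemblies for perfect and compound repeats of
    motif length 1-6 under MISA-style minimum-repeat thresholds, classifies
    the repeat landscape by motif, length class and base composition,
    designs ranked PCR primer pairs with nearest-neighbor melting
    temperatures, performs in silico PCR with per-primer mismatch and gap
    budgets to call cross-taxa transferability and amplicon length
    polymorphism, assigns loci to genomic regions from GFF3 annotation or a
    longest-ORF fallback, exports a flat marker table, and computes
    marker-assay diversity statistics (allele frequencies, expected and
    observed heterozygosity, polymorphism information content, fixation
    index, G_ST, Nei distance) with bootstrap neighbor-joining trees.
    Includes a seeded synthetic-genome generator with ground-truth manifests
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
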